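[PAD]
[UNK]
[CLS]
[SEP]
-
,
;
:
.
'
"
(
)
/
%
+
=
0
1
100-year
15
16s
18s
2
2013
2014
2015
2016
2017
2018
2019
2020
2500
2x150
2x250
3
4
454
5
6
6000
7
8
9
a
abstract
abundance
across
activated
aeration
after
aim
all
allprep
alpine
amoa
among
amplicon
amplification
amplified
an
anaerobic
analysis
and
annotation
apis
are
aries
as
assembly
at
atacama
august
b
background
based
basin
be
before
belt
benthic
benzylpenicillin
between
bgiseq-500
biofilter
biogas
bioleaching
biome
biopsy
bioreactor
bog
boreal
bos
bovine
bp
brewery
briefly
by
c
campaign
caries
catchment
cavity
cecal
cefotaxime
cell
centrifuged
challenge
characterized
chicken
clarifier
clusters
coastal
collected
collection
colon
community
comparison
composition
compost
condition
conditions
conducted
consisted
consistent
contrast
coral
cores
cpn60
d
dairy
danio
data
decreased
denitrification
dental
desert
detected
diet
digester
discussion
distal
distillery
diversity
dna
dneasy
drinking
drought
during
e
each
effluent
electrode
end
epithelium
estuary
eutrophic
extracted
f
factory
fastdna
fecal
fermentation
fermenter
fertilizer
field
fields
figure
fjord
flat
flocs
flx
following
for
forest
fornix
fragment
freshwater
from
fuel
fumigation
future
g
gallus
gene
generated
genome
gentamicin
gill
gingival
gingivitis
glacial
glacier
grassland
gravel
groundwater
gs
gut
h
higher
highlights
hiseq
hokkaido
homo
host
hot
human
hygiene
hypothesis
i
ice
illumina
immune
implications
in
increased
incubated
individuals
industrial
infant
influent
interpretation
intestinal
introduction
ion
is
isolation
it
its2
j
january
july
june
k
kelp
kept
kit
known
koji
l
lagoon
lake
lakes
landfill
layer
leaf
lesion
libraries
library
limitations
line
litter
long
low
m
main
mangrove
manual
march
marine
marker
mate
material
materials
mcra
measured
mellifera
membrane
mesotrophic
metagenome
metatranscriptome
methods
metronidazole
microbial
microbiome
microbiota
mini
minion
miniprep
miseq
mobio
mode
motivation
mouse
mucosa
mucositis
mucus
mud
mus
musculus
n
namib
namibia
nanopore
nasal
nevada
nextera
nifh
nitrogen
no
normalized
not
novaseq
o
observed
obtained
ocean
october
of
on
onsen
or
oral
oropharyngeal
our
overview
ovis
oxford
p
pacbio
paddies
pair
paired
patagonia
patient
peat
peatland
pelagic
pellets
per
performed
permafrost
pgm
pipeline
plains
plankton
plant
platform
pools
poor
porcine
posterior
powersoil
powerwater
prep
preparation
prepared
presented
previous
primer
probiotic
procedure
processed
production
profiles
profiling
protocol
purelink
purification
q
qiaamp
queensland
r
reactor
read
reads
received
reef
regime
region
relative
remains
replicates
report
rerio
results
retrieved
rhizosphere
ribosomal
rice
richness
river
rna
rna-seq
roche
rrna
rumen
run
s
salinity
saliva
saliva-associated
salt
samples
sampling
sapiens
scrofa
seawater
sediment
sediments
sequel
sequencing
shotgun
significant
silage
single
site
situated
skin
sludge
soil
sourced
spacer
specimen
specimens
spin
springs
station
stations
stool
strategy
strip
study
subject
subjects
sugarcane
suggests
summarize
supplementation
supports
surface
survey
sus
svalbard
swabs
swamp
t
taken
tank
tannery
targeted
taurus
taxa
that
the
their
this
three
throughout
tide
tissue
to
tofu
torrent
total
treatment
triplicate
tundra
two
u
unit
upwelling
using
v
vaginal
vancomycin
vessel
vinegar
w
wall
was
wastewater
water
watershed
we
were
wetland
wgs
whole
windrow
with
x
y
yunnan
z
zone
zymobiomics
##-
##,
##;
##:
##.
##.)
##'
##"
##(
##)
##/
##%
##+
##=
##0
##1
##2
##3
##4
##5
##6
##7
##8
##9
##a
##al
##b
##c
##d
##e
##ed
##er
##es
##f
##g
##h
##i
##ing
##ion
##ity
##j
##k
##l
##ly
##m
##ment
##n
##o
##ous
##p
##q
##r
##s
##t
##tion
##u
##v
##w
##x
##y
##z
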