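---
title: "Mining metagenomics metadata from publications: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining metagenomics metadata from publications: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sequence archives hold hundreds of thousands of metagenomics runs whose
usefulness for meta-analysis hinges on contextual metadata — where a sample
came from, how nucleic acid was extracted, which marker gene and primers
were amplified, on what platform it was sequenced. Much of that metadata is
absent from the submitted records but present in the narrative of the open
access article describing the study. `metamine` implements a desk-scale
version of a literature-mining pipeline that (i) classifies publications by
broad biome using labels projected from cross-referenced study records,
(ii) recognises sixteen metagenomics entity types in methods text with one
sequence labeler per type, (iii) validates those labelers by teacher–student
self-distillation, and (iv) compares the publication-derived metadata with
author-submitted study metadata over the MIxS checklist.

Everything runs offline: a synthetic-corpus generator produces documents,
curated annotations, study records, and submitted metadata with known ground
truth, so every stage of the pipeline is testable end to end.

## Distant supervision and biome classification

Study records carry a hierarchical biome lineage (up to five levels; level 1
is Engineered / Environmental / Host-associated) and cross-reference the
publications that describe them. `map_labels()` projects the level-`k` label
of each study onto its linked documents. Documents referenced by studies that
*disagree* at the requested level are dropped and reported, not kept under a
majority vote: at this corpus scale a single mislabeled training document is
costlier than a lost one, and the drop is auditable.

`balance_dataset()` retains classes with at least `min_per_class` texts
(default 20) and downsamples every retained class to the size of the
smallest, capped at `max_per_class` (default 100). Equalising to the
smallest retained class is the strictest reading of "balanced" within the
20–100 range and makes macro metrics directly comparable across classes.

Features are either TF-IDF (lowercase, punctuation stripped except
within-token hyphens, unigrams, document-frequency ≥ 2, smoothed idf
`ln((1+n)/(1+df))+1`, L2-normalised rows) or 200-dimensional paragraph
vectors. The paragraph-vector model is the distributed-bag-of-words variant
with negative sampling (window 5 stored for interface parity but unused by
DBOW; 15 epochs; learning rate 0.05 linearly decayed). Training is
single-threaded, so the `workers` parameter is a hint and determinism under
a fixed seed always holds.

The classifier is a random forest selected by grid search over
`n_estimators ∈ {50..300}` and `max_depth ∈ {25..150, unbounded}` — 42
combinations — scored by mean macro-F1 over 5-fold stratified shuffle-split
cross-validation on the 80% training split, refit on that split, and
reported on the held-out 20%. Each CV iteration draws an independent
stratified test set whose per-class counts match the corpus proportions
within one item (floor allocation plus largest remainders). Grid ties break
toward fewer trees, then shallower depth. One seed drives the split, the CV
draws, and the forest.

Triage applies the probability threshold to the **argmax class only**: a
document is selected *for* a category, so a document whose top class is
below threshold is left unselected even if the sum of lesser classes clears
it. Selection is therefore monotone non-increasing in the threshold.

## The sixteen-entity schema and BIO datasets

The schema (`entity_schema()`) covers biome metadata (ecoregion, host,
engineered, place, site, body-site, sample-material, state, date) and
experimental metadata (treatment, kit, primer, gene, library strategy,
library construction method, sequencing platform). Mentions of different
types may nest — a *site* such as "Nevada hot springs" contains the *place*
"Nevada" on the same tokens — so a single BIO tagging cannot represent all
types at once. The pipeline therefore builds **sixteen parallel datasets**
over the *same* sentences: each dataset tags only its own type's spans and
is all-O elsewhere.

Curated annotations arrive as exact text plus prefix/suffix context.
`anchor_annotations()` locates occurrences of the exact text in the
document's sentences and disambiguates repeats by the longest
suffix-of-prefix / prefix-of-suffix context match; zero-hit or still-tied
annotations land in a rejects report rather than silently vanishing.

Tokenization is a modified WordPiece: greedy longest-match-first against a
fixed subword vocabulary (one token per line, `##` continuations,
case-insensitive matching with offsets into the original text). A word that
cannot be fully segmented — long primers with prime characters, kit names,
chemical states — is emitted **whole** as a single preserved-unknown token
instead of an unknown-token marker, so such strings remain learnable.
"Cannot fully segment" is the trigger, not a length heuristic: that is
exactly the failure mode the preservation exists for. The fixture
vocabulary shipped in `inst/extdata` deliberately lacks the prime and en
dash characters so this path is always exercised.

A token belongs to a span iff their character ranges **overlap** (not
containment): robust to subword/annotation boundary mismatches at token
edges. The 90/10 train/test split is drawn **once on sentences** and reused
by all sixteen datasets, so no sentence appears in one entity's train and
another entity's test. Split sizes follow the floor rule (train =
`floor(0.9 n)`), and sentences are truncated at 128 tokens with spans that
start beyond the cut counted as unlearnable in a truncation log. By default
the sentence universe is the entity-bearing sentences (`only_annotated =
TRUE`); the flag admits the all-sentences reading too.

## The sequence labeler

The default backend is a feature-based first-order conditional sequence
model: a linear-chain CRF over tags {B, I, O} with token surface features
(lowercased identity, compressed word shape, 3-character prefix/suffix,
neighbour identities within ±2, subword-continuation and preserved-unknown
flags, bias), trained by stochastic gradient descent with per-parameter
adaptive (AdaGrad) step sizes on the per-sentence negative log-likelihood
(forward–backward gradients, mini-batches of `batch_size = 32` sentences,
deterministic LCG shuffling keyed by the seed) and decoded with Viterbi.
The adaptive steps matter here: entity tokens are rare next to the O
class, and a global step that is stable for frequent context features
under-trains the rare entity features.
It is implemented in C++ (`src/crf.cpp`) so full grid searches over sixteen
entities run in minutes on one CPU. A pretrained-transformer backend can be
plugged in by implementing the same train/predict contract; it is
deliberately not bundled — the package's contribution is the framework, and
the labeler contract (per-token B/I/O, deterministic under seed) is what
the rest of the pipeline relies on.

The hyperparameter grid uses transformer-style learning rates
{1e-5 … 5e-5} and epoch counts {10, 30, 50, 70, 90, 110, 130}. Those rate
values are conventions from fine-tuning practice; the linear model maps
them onto its SGD step by a fixed internal factor of 1e4 (so 1e-5 → 0.1),
preserving the grid's ordering and semantics — higher rate learns faster,
more epochs fit longer. Each learning rate is trained once to 130 epochs
with snapshots at every grid epoch, so the 35 evaluations cost five
training paths. Selection maximises token-wise macro-F1 on the test split;
ties break toward fewer epochs, then lower learning rate (cheaper and more
conservative models win ties).

Token-wise evaluation computes precision/recall/F1 per tag class from the
token-level confusion and macro-averages with equal weights over the
classes **present in the gold** — including O when present, taking
"token-wise" literally. A span-level view is available by decoding
(`decode_spans()`, which also repairs orphan `I` tags to `B`) and comparing
span sets, but model selection never uses it.

Whole-document annotation applies all sixteen labelers to the methods text
only — identified by tagged section types, falling back to the section
classifier for documents without a tagged methods section — and keeps
overlapping predictions across types while deduplicating within a type.

## Self-distillation validation

Teachers (labelers trained on curated data) annotate a fresh corpus:
documents classified into the three broad biomes, sampled per class at
argmax probability ≥ 0.5. The predictions — provenance-tagged `predicted`,
so the invariant "students never see a gold label" is checkable — become
the students' training data with no held-out split; the **entire curated
corpus** serves as the students' test set, which is also where their grid
search selects hyperparameters (the curated set *is* the designated test
set in this protocol, mirroring how the teachers were selected on their own
test split). A student passes when its token-wise macro-F1 against gold
reaches 70%. One distillation round only.

## The synthetic generator

`generate_bundle()` draws, from a single seeded stream in fixed order:

* documents with the five canonical sections; non-methods sentences mix
  class-specific vocabulary (fraction `mixture`, default 0.8) with shared
  vocabulary plus per-section cue words; methods sentences carry templated
  entity mentions ("DNA was extracted using the *kit*") at `plant_rate`
  (default 0.9 mentions per methods sentence, 8 methods sentences per
  document);
* per-type lexicons including multi-word forms, primer strings longer than
  20 characters with prime/dash characters, and nested site/place pairs
  that yield overlapping spans of different types;
* study records (1–2 documents each, lineages up to depth 5, ENA-style
  sample/experiment/run accessions) and submitted metadata that equals the
  planted annotation values except: a field is dropped with probability
  `metadata_missingness` (default 0.2) and replaced by a format variant
  ("June 2015" → "2015") with probability `metadata_inconsistency`
  (default 0.15).

Default problem sizes — 20 documents per class for the gold bundle, 80 per
class for fresh corpora, 60 per class selected for distillation — are the
package's study conditions: large enough that every entity type accrues
dozens of training mentions and the distillation protocol runs at the
reference selection threshold, small enough to be a desk-scale experiment.

What the generator does **not** emulate: real linguistic variation
(sentences are bag-of-words or template-slot constructions), tables and
figures (a known recall limitation of methods-text mining, since tables
often hold primers and dates), citation structure, curator disagreement,
and out-of-template entity contexts. Passing tests on this corpus
demonstrate that the machinery is correct — anchoring, tagging, training,
selection, comparison — not that the models would reach the same scores on
real publications.

## MIxS comparison

Annotation entities map to MIxS terms via an editable table
(`default_mixs_mapping()`: primer→pcr_primers, gene→target_gene,
kit→nucl_acid_ext, body-site/site→env_local_scale, state→
health_disease_stat, treatment→env_package, …); submitted field names map
via a second table. Values are canonicalized by trimming, collapsing
internal whitespace, and case-folding — **no** stemming or unit conversion,
because the comparison is of exact matches and format variants must surface
as `nonidentical` rather than be hidden. Per study and term: both sources
non-empty and intersecting → `identical` (any one shared value suffices);
non-empty and disjoint → `nonidentical`; one side only → `unique_submitted`
/ `unique_annotation`; neither → `absent`. Statuses partition the
(study, term) grid, and per-term summaries conserve study counts. The
summary's field filter (default: submitted fields observed in more than 50
studies) applies to submitted-only terms; entity-backed terms always
appear. Per-sample values are unioned to the study level before comparison,
and numeric fields are compared as strings, consistent with the exact-match
rule.

## Numerical and degenerate-input choices

* Offsets are 0-based, half-open, code-point indexed throughout.
* Whitespace is normalised (runs → single space) before sentence
  segmentation; segmentation is terminator-based with an abbreviation
  guard list and requires an upper-case/digit sentence opener.
* Empty texts transform to zero vectors and classify without error; empty
  documents annotate to empty span sets with a warning.
* An all-O training split trains a flagged degenerate labeler that
  predicts all O, rather than erroring: downstream code can detect and
  report it.
* Forest and labeler ties break deterministically (documented above), so
  a fixed seed reproduces every reported number exactly.

## Limitations

The labeler is linear in its features; it excels on templated synthetic
cues and ordinary lexical contexts but will not match a fine-tuned
transformer on real prose. Ontology normalization ships as a dictionary
contract only. Table parsing, live archive harvesting, and web-service
ontology lookups are out of scope. Macro-averaging over tag classes
including O is generous when entities are sparse; the per-entity reports
should be read together with the span-level decode when judging real-world
usefulness.
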