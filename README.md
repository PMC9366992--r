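# metamine

Metagenomics studies are only as reusable as their metadata, and much of the
metadata that sequence archives are missing — collection dates, extraction
kits, PCR primers, marker genes, body sites, sequencing platforms — is
sitting in the methods sections of the open-access articles that describe
the studies. `metamine` is an R implementation of a literature-mining
framework for recovering that metadata at desk scale, aimed at
bioinformaticians and biocurators who want to study or extend the pipeline
without archive-scale infrastructure:

* **Corpus handling** — a JATS-like article XML subset and a JSONL corpus
  dialect, with whitespace-normalised sentence segmentation and canonical
  section typing (`read_jats()`, `read_corpus_jsonl()`,
  `corpus_sentences()`).
* **Distant supervision** — biome lineages recorded on study records are
  projected onto their cross-referenced publications to label texts without
  hand-annotation; datasets are balanced (20–100 texts per class) and split
  80/20 (`map_labels()`, `balance_dataset()`, `split_train_test()`).
* **Document and section classification** — TF-IDF or 200-dimensional
  paragraph-vector features into random forests, selected over a 42-point
  `n_estimators × max_depth` grid by 5-fold stratified shuffle-split
  cross-validation, with one-vs-rest ROC reporting and probability-threshold
  triage (`train_text_classifier()`, `triage()`).
* **Named-entity recognition** — a 16-type metagenomics entity schema
  (ecoregion … sequencing platform); curated spans anchored by
  exact+prefix/suffix context; a modified WordPiece tokenizer that preserves
  unsegmentable words (long primers, kit names) instead of discarding them
  as unknown tokens; sixteen parallel BIO datasets over one shared 90/10
  sentence split; and one conditional sequence labeler per entity type
  (linear-chain CRF in C++) tuned over a 35-point learning-rate × epoch
  grid by token-wise macro-F1 (`build_entity_datasets()`,
  `train_labeler_panel()`, `annotate_corpus()`).
* **Self-distillation validation** — teachers annotate a fresh
  classifier-triaged corpus (probability ≥ 0.5, 60 documents per class);
  students are trained from scratch on those predictions only and must
  reach token-wise macro-F1 ≥ 70% against the curated corpus
  (`run_distillation_study()`, `distill()`).
* **MIxS enrichment comparison** — Europe PMC-style annotation records with
  a pluggable dictionary ontology mapper, ENA-style study XML parsing, and
  per-study/per-term comparison of publication-derived vs submitted
  metadata as identical / nonidentical / unique-to-source
  (`emit_annotations()`, `compare_studies()`, `summarize_comparison()`).
* **Synthetic ground truth** — `generate_bundle()` emits documents, curated
  annotations (including nested site/place spans and primer strings with
  out-of-vocabulary characters), study records, and submitted metadata with
  controllable missingness and format inconsistency, so the whole pipeline
  is testable offline.

The token-wise macro metrics used throughout are precision/recall/F1
computed per tag class from the token-level confusion over {B, I, O} and
averaged with equal weights over the classes present in the gold standard.

## Worked example

```r
library(metamine)

bundle <- generate_bundle(generator_config(seed = 1))
bundle
#> <mm_bundle> 60 documents, 456 annotations, 42 studies

datasets <- build_entity_datasets(bundle$documents, bundle$annotations, seed = 1)
fit <- grid_search_labeler(datasets$kit, labeler_config(seed = 1))
fit$best_report
#> # A tibble: 1 × 6
#>   entity learning_rate epoch recall precision    f1
#>   <chr>          <dbl> <int>  <dbl>     <dbl> <dbl>
#> 1 kit          0.00001    10      1         1     1

labeled  <- map_labels(bundle$studies, bundle$documents, level = 1, scope = "fulltext")
balanced <- balance_dataset(labeled, min_per_class = 5, seed = 1)
clf <- train_text_classifier(balanced, features = "tfidf", seed = 1)
glance(clf)
#> # A tibble: 1 × 8
#>   task    n_classes n_estimators max_depth macro_precision macro_recall macro_f1
#> 1 biome-…         3           50        25               1            1        1

cells <- compare_studies(bundle$studies, bundle$submitted_metadata, bundle$annotations)
summarize_comparison(cells, min_studies_per_field = 0)
#> # A tibble: 42 × 3
#>   mixs_term       status            n_studies
#> 1 env_local_scale identical                22
#> 2 env_local_scale nonidentical              3
#> 3 env_local_scale unique_annotation         5
#> 4 geo_loc_name    identical                16
#> ...
```

Reading the output: the kit labeler's grid search picked the cheapest
winning combination (learning rate 1e-5, 10 epochs) at perfect token-wise
scores on the held-out 10% — the synthetic kit mentions are strongly
templated. The biome classifier reaches macro-F1 1.0 on its held-out 20%
because the generator's class vocabularies are well separated at the
default mixture. In the comparison table, `env_local_scale` was compared in
30 studies: 22 agreed exactly, 3 disagreed only in format (the generator's
inconsistency rate), and 5 had publication-derived values with no submitted
counterpart (its missingness rate).

`autoplot(clf)` draws the per-class ROC curves; `autoplot()` on a
comparison summary draws the stacked per-term status bars; `tidy(clf)`
returns the per-class report.

A thin CLI covers the data-shuffling subcommands:

```sh
inst/scripts/metamine generate --seed 9 --out bundle/
inst/scripts/metamine build-corpus --in xml/ --out corpus.jsonl
inst/scripts/metamine map-labels --studies bundle/studies.jsonl --corpus bundle/corpus.jsonl --level 1 --out labeled.tsv
inst/scripts/metamine compare --studies bundle/studies.jsonl --annotations bundle/annotations.jsonl --submitted bundle/submitted_metadata.tsv --out report/
```

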