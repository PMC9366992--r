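Package: metamine
Title: Mining Metagenomics Metadata from Open-Access Publications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for discovering and enriching metagenomics
    study metadata from full-text publications. Reads JATS-like article XML
    into sentence-segmented corpora; builds distantly supervised biome
    classification datasets by joining study biome lineages to cross-referenced
    publications; trains TF-IDF / paragraph-vector random-forest document and
    section classifiers with grid search and stratified shuffle-split
    cross-validation; resolves curated span annotations to sentences, tokenizes
    with a modified WordPiece tokenizer that preserves out-of-vocabulary words,
    and emits per-entity BIO sequence-labeling datasets over a 16-type
    metagenomics entity schema; trains feature-based conditional sequence
    labelers with token-wise macro evaluation and teacher-student
    self-distillation validation; and compares publication-derived annotations
    against submitted study metadata over the MIxS checklist. Ships a synthetic
    corpus generator with known ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pROC,
    purrr,
    ranger,
    Rcpp,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
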