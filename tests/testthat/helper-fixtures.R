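# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code (no stored data) with fixed seeds.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

fx_vocab <- function() fx_cached("vocab", fixture_vocab)

# Small gold bundle: 8 documents per class, default separability.
fx_bundle <- function() {
  fx_cached("bundle", function() {
    generate_bundle(generator_config(
      seed = 42, corpus_label = "T",
      n_docs_per_class = c("Engineered" = 8, "Environmental" = 8,
                           "Host-associated" = 8)
    ))
  })
}

fx_datasets <- function() {
  fx_cached("datasets", function() {
    b <- fx_bundle()
    build_entity_datasets(b$documents, b$annotations, vocab = fx_vocab(),
                          seed = 42)
  })
}

# Teacher panel over the full learning-rate x epoch grids.
fx_panel <- function() {
  fx_cached("panel", function() {
    train_labeler_panel(fx_datasets(), config = labeler_config(seed = 42))
  })
}

# Biome classifier trained on the bundle with the full 42-combination grid.
fx_biome_clf <- function() {
  fx_cached("biome_clf", function() {
    b <- fx_bundle()
    labeled <- map_labels(b$studies, b$documents, level = 1,
                          scope = "fulltext")
    balanced <- balance_dataset(labeled, min_per_class = 5, seed = 42)
    train_text_classifier(balanced, features = "tfidf",
                          grid = forest_grid(), seed = 42)
  })
}

# Full distillation study at the protocol's desk scale (60 docs per class);
# shared between the self-distillation tests and the acceptance criterion.
fx_study <- function() {
  fx_cached("study", function() run_distillation_study(seed = 9))
}

# A tiny entity dataset for fast grid-search mechanics tests.
fx_tiny_kit_dataset <- function() {
  fx_cached("tiny_kit", function() {
    b <- fx_bundle()
    build_entity_datasets(b$documents, b$annotations, vocab = fx_vocab(),
                          seed = 1)[["kit"]]
  })
}

# Deterministic random BIO tag sequences for property tests.
random_tags <- function(n, p_b = 0.2, p_i = 0.2) {
  sample(c("B", "I", "O"), n, replace = TRUE,
         prob = c(p_b, p_i, 1 - p_b - p_i))
}

# Brute-force token-wise confusion metrics, kept deliberately independent
# of classification_report (simple loops over the confusion matrix).
brute_force_tokenwise <- function(pred, gold) {
  classes <- c("B", "I", "O")
  present <- classes[classes %in% gold]
  prec <- rec <- f1 <- numeric(0)
  for (cl in present) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(gold)) {
      if (pred[i] == cl && gold[i] == cl) tp <- tp + 1
      if (pred[i] == cl && gold[i] != cl) fp <- fp + 1
      if (pred[i] != cl && gold[i] == cl) fn <- fn + 1
    }
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    prec <- c(prec, p)
    rec <- c(rec, r)
    f1 <- c(f1, if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
  list(macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1))
}

# Whitespace-tokenized tokens tibble for hand-built BIO examples.
simple_tokens <- function(text) {
  m <- gregexpr("\\S+", text)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tibble::tibble(
    token_idx = seq_along(starts),
    text = substring(text, starts, starts + lens - 1L),
    char_start = starts - 1L,
    char_end = starts - 1L + lens,
    is_continuation_piece = FALSE,
    is_preserved_unknown = FALSE
  )
}
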