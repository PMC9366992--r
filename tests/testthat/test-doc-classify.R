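small_grid <- function() forest_grid(n_estimators = c(50, 100),
                                     max_depth = c(25, NA))

test_that("stratified shuffle-split folds match class proportions within one item", {
  labels <- rep(c("A", "B", "C"), c(40, 25, 10))
  folds <- cv_stratified_shuffle(labels, folds = 5, test_frac = 0.2, seed = 2)
  expect_length(folds, 5)
  for (f in folds) {
    tab <- table(factor(labels[f], levels = c("A", "B", "C")))
    expect_equal(unname(tab["A"]), 8, tolerance = 1)
    expect_equal(unname(tab["B"]), 5, tolerance = 1)
    expect_equal(unname(tab["C"]), 2, tolerance = 1)
  }
})

test_that("grid search explores the full 42-combination forest grid", {
  clf <- fx_biome_clf()
  expect_equal(nrow(clf$cv_results), 42)
  expect_equal(nrow(dplyr::distinct(clf$cv_results,
                                    n_estimators, max_depth)), 42)
})

test_that("biome classifier recovers classes on a separable synthetic corpus", {
  b <- generate_bundle(generator_config(
    seed = 31, mixture = 0.9,
    n_docs_per_class = c("Engineered" = 10, "Environmental" = 10,
                         "Host-associated" = 10)))
  labeled <- map_labels(b$studies, b$documents, 1, "fulltext")
  clf <- train_text_classifier(labeled, "tfidf", grid = small_grid(),
                               seed = 9)
  macro <- clf$report$f1[clf$report$class == "macro avg"]
  expect_gte(macro, 0.9)
  expect_true(all(clf$report$f1 >= 0, clf$report$f1 <= 1))
  expect_equal(sum(clf$report$support[clf$report$class != "macro avg"]),
               clf$report$support[clf$report$class == "macro avg"])
})

test_that("permuted labels score near chance", {
  b <- fx_bundle()
  labeled <- map_labels(b$studies, b$documents, 1, "fulltext")
  macros <- vapply(1:3, function(s) {
    perm <- labeled
    perm$label <- withr::with_seed(s, sample(perm$label))
    clf <- train_text_classifier(perm, "tfidf", grid = small_grid(),
                                 seed = 9)
    clf$report$f1[clf$report$class == "macro avg"]
  }, 1)
  expect_lt(abs(mean(macros) - 1 / 3), 0.15 + 1e-9)
})

test_that("training is deterministic under a fixed seed", {
  b <- fx_bundle()
  labeled <- map_labels(b$studies, b$documents, 1, "fulltext")
  c1 <- train_text_classifier(labeled, "tfidf", grid = small_grid(), seed = 4)
  c2 <- train_text_classifier(labeled, "tfidf", grid = small_grid(), seed = 4)
  expect_equal(c1$n_estimators, c2$n_estimators)
  expect_equal(c1$max_depth, c2$max_depth)
  expect_equal(c1$report, c2$report)
  expect_equal(c1$cv_results, c2$cv_results)
})

test_that("predicted probabilities are a distribution and argmax matches class-pure text", {
  clf <- fx_biome_clf()
  b <- fx_bundle()
  doc <- b$documents[b$biome_labels$class == "Host-associated", ][1, ]
  probs <- predict_proba(clf, c(document_text(doc), ""))
  expect_equal(unname(rowSums(as.matrix(probs))), c(1, 1), tolerance = 1e-9)
  expect_true(all(as.matrix(probs) >= 0))
  expect_equal(names(probs)[which.max(as.matrix(probs)[1, ])],
               "Host-associated")
})

test_that("triage selects the argmax class at or above the threshold", {
  probs <- tibble::tibble(
    doc_id = c("d1", "d2", "d3"),
    env = c(0.45, 0.39, 0.2),
    eng = c(0.35, 0.36, 0.5),
    host = c(0.20, 0.25, 0.3)
  )
  out <- triage(probs, threshold = 0.4)
  expect_equal(out$doc_id, c("d1", "d3"))
  expect_equal(out$class, c("env", "eng"))
  # boundary: exactly at threshold is selected; just below is not
  expect_false("d2" %in% out$doc_id)
  expect_true("d3" %in% triage(probs, 0.5)$doc_id)
  # zero threshold selects everything
  expect_equal(nrow(triage(probs, 0)), 3)
})

test_that("triage selection is monotone non-increasing in the threshold", {
  clf <- fx_biome_clf()
  b <- fx_bundle()
  texts <- vapply(seq_len(nrow(b$documents)), function(i) {
    document_text(b$documents[i, ])
  }, "")
  probs <- predict_proba(clf, texts)
  probs$doc_id <- b$documents$doc_id
  sizes <- vapply(seq(0, 1, by = 0.1), function(t) nrow(triage(probs, t)), 1L)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], nrow(b$documents))
})

test_that("ROC curves are valid and near-perfect on the separable corpus", {
  clf <- fx_biome_clf()
  aucs <- unique(clf$roc[, c("class", "auc")])
  expect_equal(nrow(aucs), 3)
  expect_true(all(aucs$auc >= 0, aucs$auc <= 1))
  expect_true(all(aucs$auc >= 0.95))
  p <- ggplot2::ggplot_build(autoplot(clf))
  expect_gt(nrow(p$data[[1]]), 0)
})

test_that("tidy and glance expose the held-out report", {
  clf <- fx_biome_clf()
  td <- tidy(clf)
  expect_true(all(c("class", "precision", "recall", "f1", "support") %in%
                    names(td)))
  gl <- glance(clf)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$macro_f1, td$f1[td$class == "macro avg"])
})

test_that("section classifier learns the five canonical types", {
  b <- fx_bundle()
  sents <- corpus_sentences(b$documents)
  secs <- sents |>
    dplyr::group_by(doc_id, section_idx, canonical_type) |>
    dplyr::summarise(text = paste(text, collapse = " "), .groups = "drop")
  clf <- train_section_classifier(secs$text, secs$canonical_type,
                                  grid = small_grid(), seed = 9)
  expect_equal(clf$task, "section")
  expect_setequal(clf$classes, c("abstract", "introduction", "methods",
                                 "results", "discussion"))
  expect_gte(clf$report$f1[clf$report$class == "macro avg"], 0.8)
  expect_error(train_section_classifier("x", "other"), "canonical")
  assign("section_clf", clf, envir = .fx)
})

test_that("extract_methods_text prefers tagged sections and falls back to the classifier", {
  b <- fx_bundle()
  doc <- b$documents[1, ]
  tagged <- extract_methods_text(doc)
  expect_equal(tagged, document_text(doc, "methods"))

  sec_clf <- get("section_clf", envir = .fx)
  untagged <- doc
  untagged$sections[[1]]$canonical_type <- "other"
  expect_equal(extract_methods_text(untagged, sec_clf), tagged)

  empty <- new_document("e1")
  expect_warning(out <- extract_methods_text(empty), "no sections")
  expect_equal(out, "")
})

test_that("degenerate single-class input is rejected", {
  x <- matrix(runif(20), ncol = 2)
  expect_error(train_classifier(x, rep("A", 10), small_grid()), "2 classes")
})
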