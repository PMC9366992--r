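# Random-forest document and section classifiers over TF-IDF or
# paragraph-vector features, with grid search selected by stratified
# shuffle-split cross-validation and a probability-thresholded triage rule.

#' Random forest hyperparameter grid
#'
#' @param n_estimators Candidate numbers of trees.
#' @param max_depth Candidate maximum depths; `NA` means unbounded.
#' @param cv_folds Number of shuffle-split cross-validation iterations.
#' @param cv_test_frac Held-out fraction per CV iteration.
#' @return An object of class `forest_grid`.
#' @export
forest_grid <- function(n_estimators = c(50, 100, 150, 200, 250, 300),
                        max_depth = c(25, 50, 75, 100, 125, 150, NA),
                        cv_folds = 5, cv_test_frac = 0.2) {
  stopifnot(length(n_estimators) > 0, length(max_depth) > 0, cv_folds >= 1)
  structure(
    list(
      n_estimators = n_estimators, max_depth = max_depth,
      cv_folds = cv_folds, cv_test_frac = cv_test_frac
    ),
    class = "forest_grid"
  )
}

# Per-class allocation of a stratified test draw: floor + largest remainder.
stratified_test_sizes <- function(class_counts, test_frac) {
  raw <- class_counts * test_frac
  base <- floor(raw)
  want <- round(sum(raw))
  rem <- raw - base
  extra <- want - sum(base)
  if (extra > 0) {
    order_rem <- order(rem, decreasing = TRUE)
    base[order_rem[seq_len(extra)]] <- base[order_rem[seq_len(extra)]] + 1
  }
  pmin(pmax(base, ifelse(class_counts > 1, 1, 0)), class_counts - 1)
}

#' Stratified shuffle-split cross-validation folds
#'
#' Each fold is an independent random draw of a stratified test set whose
#' per-class proportions match the corpus within one item per class.
#'
#' @param labels Vector of class labels.
#' @param folds Number of iterations.
#' @param test_frac Held-out fraction.
#' @param seed Integer seed.
#' @return A list of integer vectors (test indices per fold).
#' @export
cv_stratified_shuffle <- function(labels, folds = 5, test_frac = 0.2,
                                  seed = 1) {
  idx_by_class <- split(seq_along(labels), labels)
  counts <- lengths(idx_by_class)
  sizes <- stratified_test_sizes(counts, test_frac)
  with_local_seed(seed, {
    lapply(seq_len(folds), function(f) {
      sort(unlist(purrr::map2(idx_by_class, sizes, function(idx, k) {
        if (k == 0) integer(0) else sample(idx, k)
      }), use.names = FALSE))
    })
  })
}

as_feature_matrix <- function(features) {
  m <- as.matrix(features)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

fit_forest <- function(x, y, n_estimators, max_depth, seed) {
  ranger::ranger(
    x = x, y = factor(y),
    num.trees = n_estimators,
    max.depth = if (is.na(max_depth)) 0 else max_depth,
    probability = TRUE,
    seed = seed,
    num.threads = 1
  )
}

forest_proba <- function(model, x) {
  p <- stats::predict(model, data = x, num.threads = 1)$predictions
  p[, sort(colnames(p)), drop = FALSE]
}

proba_to_class <- function(p) {
  colnames(p)[max.col(p, ties.method = "first")]
}

#' Per-class precision/recall/F1 report for class predictions
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param classes Class set to report on (defaults to classes in `truth`).
#' @return A tibble with columns `class`, `precision`, `recall`, `f1`,
#'   `support`, plus a final `"macro avg"` row (unweighted mean, support =
#'   total).
#' @export
classification_report <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(truth)))
  truth <- as.character(truth)
  pred <- as.character(pred)
  rows <- purrr::map(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble::tibble(class = cl, precision = precision, recall = recall,
                   f1 = f1, support = sum(truth == cl))
  })
  per_class <- dplyr::bind_rows(rows)
  macro <- tibble::tibble(
    class = "macro avg",
    precision = mean(per_class$precision),
    recall = mean(per_class$recall),
    f1 = mean(per_class$f1),
    support = length(truth)
  )
  dplyr::bind_rows(per_class, macro)
}

macro_f1 <- function(truth, pred, classes = NULL) {
  rep <- classification_report(truth, pred, classes)
  rep$f1[rep$class == "macro avg"]
}

roc_curves <- function(truth, proba) {
  classes <- colnames(proba)
  purrr::map(classes, function(cl) {
    resp <- factor(ifelse(truth == cl, cl, "rest"), levels = c("rest", cl))
    if (length(unique(resp)) < 2) return(NULL)
    r <- pROC::roc(resp, proba[, cl], quiet = TRUE, direction = "<")
    tibble::tibble(
      class = cl,
      fpr = rev(1 - r$specificities),
      tpr = rev(r$sensitivities),
      auc = as.numeric(r$auc)
    )
  }) |>
    purrr::compact() |>
    dplyr::bind_rows()
}

#' Train a random forest classifier with grid search
#'
#' Splits the data 80/20 (stratified), selects `(n_estimators, max_depth)`
#' by mean macro-F1 over stratified shuffle-split cross-validation on the
#' training split, refits the winner on the full training split, and
#' reports held-out precision/recall/F1 per class plus one-vs-rest ROC
#' curves. Grid ties break toward fewer trees, then shallower depth.
#'
#' @param features Numeric matrix (or sparse matrix) of row-aligned features.
#' @param labels Class labels aligned to `features` rows (at least 2
#'   classes).
#' @param grid A [forest_grid()].
#' @param seed Integer seed driving the split, the CV draws, and the forest.
#' @param task Task tag stored on the result (e.g. `"biome-level-1"`,
#'   `"section"`).
#' @param train_frac Training fraction of the outer split.
#' @return An object of class `trained_classifier`.
#' @export
train_classifier <- function(features, labels, grid = forest_grid(),
                             seed = 9, task = "biome-level-1",
                             train_frac = 0.8) {
  x <- as_feature_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("need at least 2 classes to train a classifier", call. = FALSE)
  }

  idx <- tibble::tibble(row = seq_len(nrow(x)), label = labels)
  sp <- split_train_test(idx, train_frac = train_frac, seed = seed)
  x_train <- x[sp$train$row, , drop = FALSE]
  y_train <- labels[sp$train$row]
  x_test <- x[sp$test$row, , drop = FALSE]
  y_test <- labels[sp$test$row]

  folds <- cv_stratified_shuffle(y_train, folds = grid$cv_folds,
                                 test_frac = grid$cv_test_frac, seed = seed)
  combos <- tidyr::expand_grid(
    n_estimators = grid$n_estimators, max_depth = grid$max_depth
  )
  cv_results <- purrr::pmap(combos, function(n_estimators, max_depth) {
    scores <- purrr::map_dbl(folds, function(test_idx) {
      tr <- setdiff(seq_along(y_train), test_idx)
      m <- fit_forest(x_train[tr, , drop = FALSE], y_train[tr],
                      n_estimators, max_depth, seed)
      pred <- proba_to_class(forest_proba(m, x_train[test_idx, , drop = FALSE]))
      macro_f1(y_train[test_idx], pred, classes = sort(unique(y_train)))
    })
    tibble::tibble(
      n_estimators = n_estimators, max_depth = max_depth,
      cv_macro_f1 = mean(scores)
    )
  }) |>
    dplyr::bind_rows()

  ordered <- cv_results |>
    arrange(desc(.data$cv_macro_f1), .data$n_estimators, .data$max_depth)
  best <- ordered[1, ]

  model <- fit_forest(x_train, y_train, best$n_estimators, best$max_depth,
                      seed)
  proba <- forest_proba(model, x_test)
  pred <- proba_to_class(proba)
  report <- classification_report(y_test, pred,
                                  classes = sort(unique(labels)))
  roc <- roc_curves(y_test, proba)

  structure(
    list(
      task = task,
      classes = sort(unique(labels)),
      n_estimators = best$n_estimators,
      max_depth = best$max_depth,
      model = model,
      report = report,
      roc = roc,
      cv_results = cv_results,
      seed = seed,
      featurizer = NULL,
      feature_names = colnames(x)
    ),
    class = "trained_classifier"
  )
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("<trained_classifier>", x$task, "| classes:",
      paste(x$classes, collapse = ", "), "\n")
  cat("  n_estimators =", x$n_estimators, ", max_depth =",
      ifelse(is.na(x$max_depth), "unbounded", x$max_depth), "\n")
  cat("  test macro F1 =",
      round(x$report$f1[x$report$class == "macro avg"], 3), "\n")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.trained_classifier <- function(x, ...) {
  x$report
}

#' @export
#' @importFrom generics glance
glance.trained_classifier <- function(x, ...) {
  macro <- x$report[x$report$class == "macro avg", ]
  tibble::tibble(
    task = x$task,
    n_classes = length(x$classes),
    n_estimators = x$n_estimators,
    max_depth = x$max_depth,
    macro_precision = macro$precision,
    macro_recall = macro$recall,
    macro_f1 = macro$f1,
    mean_auc = if (nrow(x$roc) > 0) mean(unique(x$roc[, c("class", "auc")])$auc)
      else NA_real_
  )
}

#' Plot one-vs-rest ROC curves of a trained classifier
#'
#' @param object A `trained_classifier`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.trained_classifier <- function(object, ...) {
  stopifnot(nrow(object$roc) > 0)
  lab <- object$roc |>
    distinct(.data$class, .data$auc) |>
    mutate(label = sprintf("%s (AUC %.2f)", .data$class, .data$auc))
  dat <- object$roc |>
    left_join(lab, by = c("class", "auc"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      colour = NULL, title = paste("One-vs-rest ROC:", object$task)
    ) +
    ggplot2::theme_minimal()
}

featurize_texts <- function(classifier, texts) {
  f <- classifier$featurizer
  if (is.null(f)) stop("classifier has no featurizer", call. = FALSE)
  m <- if (inherits(f, "tfidf_model")) {
    as.matrix(tfidf_transform(f, texts))
  } else {
    infer_docvec(f, texts, seed = classifier$seed)
  }
  colnames(m) <- classifier$feature_names
  m
}

#' Train a text classifier (featurizer + random forest)
#'
#' Convenience wrapper binding a TF-IDF or paragraph-vector featurizer to
#' [train_classifier()], so the result can score raw text via
#' [predict_proba()].
#'
#' @param labeled A tibble with columns `text` and `label` (as from
#'   [map_labels()] / [balance_dataset()]).
#' @param features `"tfidf"` or `"doc2vec"`.
#' @param grid A [forest_grid()].
#' @param seed Integer seed.
#' @param task Task tag.
#' @param ... Passed to the featurizer fit.
#' @return A `trained_classifier` carrying its featurizer.
#' @export
train_text_classifier <- function(labeled, features = c("tfidf", "doc2vec"),
                                  grid = forest_grid(), seed = 9,
                                  task = "biome-level-1", ...) {
  features <- match.arg(features)
  featurizer <- if (features == "tfidf") {
    fit_tfidf(labeled$text, ...)
  } else {
    fit_doc_embeddings(labeled$text, seed = seed, ...)
  }
  x <- if (features == "tfidf") {
    as.matrix(tfidf_transform(featurizer, labeled$text))
  } else {
    featurizer$docvecs
  }
  clf <- train_classifier(x, labeled$label, grid = grid, seed = seed,
                          task = task)
  clf$featurizer <- featurizer
  clf$feature_names <- colnames(as_feature_matrix(x))
  clf
}

#' Predict class probabilities for texts
#'
#' @param classifier A `trained_classifier` with a featurizer.
#' @param texts Character vector (an empty text yields a valid
#'   distribution).
#' @return A tibble with one row per text and one probability column per
#'   class; rows sum to 1.
#' @export
predict_proba <- function(classifier, texts) {
  stopifnot(inherits(classifier, "trained_classifier"))
  if (is.null(classifier$model)) stop("classifier is not fitted", call. = FALSE)
  x <- featurize_texts(classifier, texts)
  tibble::as_tibble(as.data.frame(forest_proba(classifier$model, x)))
}

#' Probability-thresholded triage
#'
#' A document is selected for its argmax class iff that class's probability
#' meets the threshold. Selection is monotone non-increasing in the
#' threshold.
#'
#' @param doc_probs A tibble with a `doc_id` column and one probability
#'   column per class (as from [predict_proba()] plus ids).
#' @param threshold Probability threshold in `[0, 1]`.
#' @return A tibble `doc_id`, `class`, `prob` of selected documents.
#' @export
triage <- function(doc_probs, threshold = 0.4) {
  stopifnot(threshold >= 0, threshold <= 1)
  classes <- setdiff(names(doc_probs), "doc_id")
  p <- as.matrix(doc_probs[, classes])
  best <- max.col(p, ties.method = "first")
  out <- tibble::tibble(
    doc_id = doc_probs$doc_id,
    class = classes[best],
    prob = p[cbind(seq_len(nrow(p)), best)]
  )
  out |> filter(.data$prob >= threshold)
}

#' Train the section classifier
#'
#' Same machinery as [train_text_classifier()] with the five canonical
#' section types as the label set.
#'
#' @param section_texts Character vector of section texts.
#' @param section_labels Canonical section type per text (no `"other"`).
#' @param grid A [forest_grid()].
#' @param seed Integer seed.
#' @param features `"tfidf"` or `"doc2vec"`.
#' @return A `trained_classifier` with task `"section"`.
#' @export
train_section_classifier <- function(section_texts, section_labels,
                                     grid = forest_grid(), seed = 9,
                                     features = "tfidf") {
  allowed <- setdiff(canonical_section_types(), "other")
  bad <- setdiff(unique(section_labels), allowed)
  if (length(bad) > 0) {
    stop("section labels must be canonical types; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  train_text_classifier(
    tibble::tibble(text = section_texts, label = section_labels),
    features = features, grid = grid, seed = seed, task = "section"
  )
}

#' Extract the methods text of a document
#'
#' Returns the concatenated text of sections tagged `methods`; when none is
#' tagged, each section's text is classified and the sections predicted
#' `methods` are concatenated; when still none, an empty string is returned
#' with a warning.
#'
#' @param document A one-row corpus tibble.
#' @param section_classifier Optional `trained_classifier` with task
#'   `"section"` used for the fallback path.
#' @return A single string.
#' @export
extract_methods_text <- function(document, section_classifier = NULL) {
  stopifnot(nrow(document) == 1)
  secs <- document$sections[[1]]
  if (nrow(secs) == 0) {
    warning("document ", document$doc_id, " has no sections", call. = FALSE)
    return("")
  }
  tagged <- secs$canonical_type == "methods"
  if (any(tagged)) {
    texts <- purrr::map_chr(secs$sentences[tagged], section_text)
    return(paste(texts[nzchar(texts)], collapse = " "))
  }
  if (is.null(section_classifier)) {
    warning("no tagged methods section and no section classifier",
            call. = FALSE)
    return("")
  }
  texts <- purrr::map_chr(secs$sentences, section_text)
  probs <- predict_proba(section_classifier, texts)
  pred <- proba_to_class(as.matrix(probs))
  keep <- pred == "methods" & nzchar(texts)
  if (!any(keep)) {
    warning("no section predicted as methods for ", document$doc_id,
            call. = FALSE)
    return("")
  }
  paste(texts[keep], collapse = " ")
}
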