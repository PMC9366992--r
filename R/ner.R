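# One sequence labeler per entity type. The default backend is a
# feature-based first-order conditional sequence model (linear-chain CRF,
# SGD-trained, Viterbi-decoded; see src/crf.cpp) over token surface
# features; a pretrained-transformer backend can be plugged in by
# implementing the same train/predict contract.

TAG_LEVELS <- c("B", "I", "O")

#' Sequence labeler configuration
#'
#' @param learning_rate_grid Candidate learning rates.
#' @param epoch_grid Candidate training epoch counts.
#' @param batch_size Sentences per SGD update.
#' @param max_len Maximum tokens per sentence.
#' @param seed Integer seed (drives the SGD shuffling).
#' @param backend Labeler backend; only `"feature-sequence"` ships.
#' @return An object of class `labeler_config`.
#' @export
labeler_config <- function(learning_rate_grid = c(1e-5, 2e-5, 3e-5, 4e-5, 5e-5),
                           epoch_grid = c(10, 30, 50, 70, 90, 110, 130),
                           batch_size = 32, max_len = 128, seed = 9,
                           backend = "feature-sequence") {
  stopifnot(length(learning_rate_grid) > 0, length(epoch_grid) > 0,
            batch_size >= 1)
  if (!identical(backend, "feature-sequence")) {
    stop("backend '", backend, "' is not available; the default is ",
         "'feature-sequence'", call. = FALSE)
  }
  structure(
    list(
      learning_rate_grid = learning_rate_grid,
      epoch_grid = sort(as.integer(epoch_grid)),
      batch_size = as.integer(batch_size),
      max_len = as.integer(max_len),
      seed = as.integer(seed),
      backend = backend
    ),
    class = "labeler_config"
  )
}

word_shape <- function(x) {
  s <- gsub("[A-Z]", "X", x)
  s <- gsub("[a-z]", "x", s)
  s <- gsub("[0-9]", "d", s)
  s <- gsub("[^Xxd]", "_", s)
  gsub("(.)\\1+", "\\1", s)
}

# Surface features per token: identity, shape, character prefix/suffix,
# neighbour identities within +/-2, subword flags, bias.
featurize_tokens <- function(tokens) {
  n <- nrow(tokens)
  if (n == 0) return(list())
  lower <- tolower(tokens$text)
  padded <- c("<s>", "<s>", lower, "</s>", "</s>")
  purrr::map(seq_len(n), function(i) {
    c(
      paste0("w=", lower[i]),
      paste0("shape=", word_shape(tokens$text[i])),
      paste0("pre3=", substr(lower[i], 1, 3)),
      paste0("suf3=", substring(lower[i], max(1, nchar(lower[i]) - 2))),
      paste0("w-1=", padded[i + 1]),
      paste0("w-2=", padded[i]),
      paste0("w+1=", padded[i + 3]),
      paste0("w+2=", padded[i + 4]),
      if (tokens$is_continuation_piece[i]) "cont" else NULL,
      if (tokens$is_preserved_unknown[i]) "punk" else NULL,
      "bias"
    )
  })
}

features_to_ids <- function(feat_list, index) {
  purrr::map(feat_list, function(fs) {
    ids <- match(fs, index)
    as.integer(ids[!is.na(ids)] - 1L)
  })
}

tags_to_ids <- function(tags) {
  as.integer(match(tags, TAG_LEVELS) - 1L)
}

ids_to_tags <- function(ids) {
  TAG_LEVELS[ids + 1L]
}

prepare_training <- function(sentences) {
  feats <- purrr::map(sentences, function(ts) featurize_tokens(ts$tokens))
  index <- unique(unlist(feats, use.names = FALSE))
  list(
    index = index,
    feat_ids = purrr::map(feats, features_to_ids, index = index),
    tag_ids = purrr::map(sentences, function(ts) tags_to_ids(ts$tags))
  )
}

new_labeler <- function(entity_type, index, params, learning_rate, epochs,
                        config, degenerate) {
  structure(
    list(
      entity_type = entity_type,
      backend = config$backend,
      feature_index = index,
      W = params$W,
      trans = params$trans,
      start = params$start,
      learning_rate = learning_rate,
      epochs = epochs,
      batch_size = config$batch_size,
      seed = config$seed,
      degenerate = degenerate
    ),
    class = "sequence_labeler"
  )
}

#' @export
print.sequence_labeler <- function(x, ...) {
  cat("<sequence_labeler>", x$entity_type, "| backend", x$backend,
      "| lr", format(x$learning_rate), "| epochs", x$epochs,
      if (x$degenerate) "| degenerate (all-O training data)" else "", "\n")
  invisible(x)
}

#' Train a sequence labeler for one entity type
#'
#' Fits the feature-based conditional sequence model on the dataset's
#' training split at a single `(learning_rate, epochs)` point. Training is
#' deterministic given the config seed. A training split without a single
#' `B` tag yields a model flagged degenerate (it will predict all `O`).
#'
#' @param dataset An `entity_dataset` (or a list of tagged sentences, taken
#'   as the training split).
#' @param learning_rate SGD learning rate (transformer-style scale).
#' @param epochs Training passes.
#' @param config A [labeler_config()].
#' @return A `sequence_labeler`.
#' @export
train_labeler <- function(dataset, learning_rate = 3e-5, epochs = 50,
                          config = labeler_config()) {
  train <- if (inherits(dataset, "entity_dataset")) dataset$train else dataset
  entity_type <- if (inherits(dataset, "entity_dataset")) dataset$entity_type
    else "unknown"
  if (length(train) == 0) stop("empty training split", call. = FALSE)
  prep <- prepare_training(train)
  degenerate <- !any(unlist(purrr::map(train, "tags")) == "B")
  snaps <- .crf_train_path(
    prep$feat_ids, prep$tag_ids, length(prep$index),
    learning_rate, as.integer(epochs), config$batch_size, config$seed
  )
  new_labeler(entity_type, prep$index, snaps[[1]], learning_rate,
              as.integer(epochs), config, degenerate)
}

#' Predict BIO tags for tokenized sentences
#'
#' @param labeler A `sequence_labeler`.
#' @param sentences A list of tagged/tokenized sentences (each with a
#'   `tokens` tibble), or a single tokens tibble.
#' @return A list of character tag vectors (or a single vector when a
#'   single tokens tibble was given).
#' @export
predict_tags <- function(labeler, sentences) {
  stopifnot(inherits(labeler, "sequence_labeler"))
  single <- is.data.frame(sentences)
  if (single) sentences <- list(list(tokens = sentences))
  feats <- purrr::map(sentences, function(ts) featurize_tokens(ts$tokens))
  ids <- purrr::map(feats, features_to_ids, index = labeler$feature_index)
  out <- .crf_viterbi(ids, labeler$W, labeler$trans, labeler$start)
  out <- purrr::map(out, ids_to_tags)
  if (single) out[[1]] else out
}

#' Token-wise evaluation report
#'
#' Per-tag-class precision/recall/F1 from the token-level confusion over
#' `{B, I, O}`; the macro average is the unweighted mean over classes
#' present in the gold tags. A class's F1 is 0 when precision and recall
#' are both 0.
#'
#' @param pred_tags Predicted tags: a character vector or list of vectors.
#' @param gold_tags Gold tags, same shape as `pred_tags`.
#' @return A list with `report` (tibble `class`, `precision`, `recall`,
#'   `f1`, `support`, plus `"macro avg"`), and scalars `macro_precision`,
#'   `macro_recall`, `macro_f1`.
#' @export
evaluate_tokenwise <- function(pred_tags, gold_tags) {
  if (is.list(pred_tags)) {
    if (length(pred_tags) != length(gold_tags) ||
        !all(lengths(pred_tags) == lengths(gold_tags))) {
      stop("pred and gold tag sequences have mismatched lengths",
           call. = FALSE)
    }
    pred_tags <- unlist(pred_tags, use.names = FALSE)
    gold_tags <- unlist(gold_tags, use.names = FALSE)
  }
  if (length(pred_tags) != length(gold_tags)) {
    stop("pred and gold tag sequences have mismatched lengths", call. = FALSE)
  }
  present <- TAG_LEVELS[TAG_LEVELS %in% unique(gold_tags)]
  report <- classification_report(gold_tags, pred_tags, classes = present)
  macro <- report[report$class == "macro avg", ]
  list(
    report = report,
    macro_precision = macro$precision,
    macro_recall = macro$recall,
    macro_f1 = macro$f1
  )
}

evaluate_labeler <- function(labeler, sentences) {
  pred <- predict_tags(labeler, sentences)
  gold <- purrr::map(sentences, "tags")
  evaluate_tokenwise(pred, gold)
}

#' Grid search over learning rates and epochs for one entity labeler
#'
#' Trains every `(learning_rate, epochs)` combination (one SGD path per
#' learning rate, snapshotted at each epoch checkpoint), evaluates each on
#' the dataset's test split token-wise, and selects the maximum macro-F1;
#' ties break toward fewer epochs, then lower learning rate.
#'
#' @param dataset An `entity_dataset`.
#' @param config A [labeler_config()].
#' @param eval_sentences Optional list of tagged sentences to evaluate on
#'   instead of the dataset's own test split.
#' @return A list with `best` (a `sequence_labeler`), `reports` (one row
#'   per combination: `entity`, `learning_rate`, `epoch`, `recall`,
#'   `precision`, `f1`), and `best_report`.
#' @export
grid_search_labeler <- function(dataset, config = labeler_config(),
                                eval_sentences = NULL) {
  stopifnot(inherits(dataset, "entity_dataset"))
  test <- if (is.null(eval_sentences)) dataset$test else eval_sentences
  if (length(dataset$train) == 0) stop("empty training split", call. = FALSE)
  if (length(test) == 0) stop("empty evaluation split", call. = FALSE)

  prep <- prepare_training(dataset$train)
  degenerate <- !any(unlist(purrr::map(dataset$train, "tags")) == "B")
  test_feats <- purrr::map(test, function(ts) featurize_tokens(ts$tokens))
  test_ids <- purrr::map(test_feats, features_to_ids, index = prep$index)
  gold <- purrr::map(test, "tags")

  rows <- list()
  snapshots <- list()
  for (lr in config$learning_rate_grid) {
    snaps <- .crf_train_path(
      prep$feat_ids, prep$tag_ids, length(prep$index),
      lr, config$epoch_grid, config$batch_size, config$seed
    )
    for (e in seq_along(config$epoch_grid)) {
      pred_ids <- .crf_viterbi(test_ids, snaps[[e]]$W, snaps[[e]]$trans,
                               snaps[[e]]$start)
      ev <- evaluate_tokenwise(purrr::map(pred_ids, ids_to_tags), gold)
      rows[[length(rows) + 1]] <- tibble::tibble(
        entity = dataset$entity_type,
        learning_rate = lr,
        epoch = config$epoch_grid[e],
        recall = ev$macro_recall,
        precision = ev$macro_precision,
        f1 = ev$macro_f1
      )
      snapshots[[length(snapshots) + 1]] <- snaps[[e]]
    }
  }
  reports <- dplyr::bind_rows(rows)
  pick <- reports |>
    mutate(.row = dplyr::row_number()) |>
    arrange(desc(.data$f1), .data$epoch, .data$learning_rate) |>
    slice(1)
  best <- new_labeler(
    dataset$entity_type, prep$index, snapshots[[pick$.row]],
    pick$learning_rate, pick$epoch, config, degenerate
  )
  list(best = best, reports = reports, best_report = pick |> select(-".row"))
}

#' Train the full panel of entity labelers
#'
#' Runs [grid_search_labeler()] for every entity dataset.
#'
#' @param datasets An `entity_datasets` object (16 types).
#' @param config A [labeler_config()].
#' @return A list with `labelers` (named list of `sequence_labeler`) and
#'   `reports` (best row per entity, shaped entity / learning_rate / epoch /
#'   recall / precision / f1).
#' @export
train_labeler_panel <- function(datasets, config = labeler_config()) {
  fits <- purrr::map(datasets, grid_search_labeler, config = config)
  list(
    labelers = purrr::map(fits, "best"),
    reports = dplyr::bind_rows(purrr::map(fits, "best_report")),
    all_reports = dplyr::bind_rows(purrr::map(fits, "reports"))
  )
}

#' Decode BIO tags back to character spans
#'
#' Maximal runs starting at `B` become spans; an `I` with no preceding
#' `B`/`I` is repaired to `B` (counted in the `repairs` attribute). A
#' span's character range runs from its first token's start to its last
#' token's end; `exact` is sliced from the sentence text.
#'
#' @param tagged A tagged sentence: list with `tokens`, `tags`, `text`, and
#'   optionally `sent_id`, `doc_id`, `entity_type`.
#' @return A tibble of predicted spans (`doc_id`, `sent_id`, `entity_type`,
#'   `char_start`, `char_end`, `exact`).
#' @export
decode_spans <- function(tagged) {
  tags <- tagged$tags
  tokens <- tagged$tokens
  n <- length(tags)
  repairs <- 0L
  if (n > 0) {
    for (i in seq_len(n)) {
      if (tags[i] == "I" && (i == 1 || tags[i - 1] == "O")) {
        tags[i] <- "B"
        repairs <- repairs + 1L
      }
    }
  }
  starts <- which(tags == "B")
  spans <- purrr::map(starts, function(s) {
    e <- s
    while (e < n && tags[e + 1] == "I") e <- e + 1
    tibble::tibble(
      char_start = tokens$char_start[s],
      char_end = tokens$char_end[e]
    )
  })
  out <- if (length(spans)) dplyr::bind_rows(spans) else
    tibble::tibble(char_start = integer(), char_end = integer())
  text <- if (is.null(tagged$text)) detokenize(tokens) else tagged$text
  exact <- if (nrow(out) == 0) character(0) else
    substring(text, out$char_start + 1, out$char_end)
  out <- tibble::tibble(
    doc_id = if (is.null(tagged$doc_id)) NA_character_ else tagged$doc_id,
    sent_id = if (is.null(tagged$sent_id)) NA_character_ else tagged$sent_id,
    entity_type = if (is.null(tagged$entity_type)) NA_character_ else
      tagged$entity_type,
    out,
    exact = exact
  )
  attr(out, "repairs") <- repairs
  out
}

methods_sentences <- function(document, section_classifier = NULL) {
  secs <- document$sections[[1]]
  if (nrow(secs) == 0) return(NULL)
  keep <- secs$canonical_type == "methods"
  if (!any(keep) && !is.null(section_classifier)) {
    texts <- purrr::map_chr(secs$sentences, section_text)
    probs <- predict_proba(section_classifier, texts)
    keep <- proba_to_class(as.matrix(probs)) == "methods" & nzchar(texts)
  }
  if (!any(keep)) return(NULL)
  dplyr::bind_rows(secs$sentences[keep])
}

#' Annotate a document's methods text with the labeler panel
#'
#' Extracts the methods sentences (tagged sections, falling back to the
#' section classifier), tokenizes them, applies every entity labeler
#' independently, and decodes the predicted spans. Overlapping spans across
#' entity types are kept; exact duplicates within a type are removed.
#'
#' @param document A one-row corpus tibble.
#' @param labelers Named list of `sequence_labeler`, one per schema type.
#' @param vocab A `wordpiece_vocab`.
#' @param section_classifier Optional section `trained_classifier` for
#'   documents without a tagged methods section.
#' @return A tibble of predicted spans with `provenance = "predicted"`.
#' @export
annotate_document <- function(document, labelers, vocab = fixture_vocab(),
                              section_classifier = NULL) {
  missing <- setdiff(entity_types(), names(labelers))
  if (length(missing) > 0) {
    stop("missing labeler(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  empty <- tibble::tibble(
    doc_id = character(), sent_id = character(), entity_type = character(),
    char_start = integer(), char_end = integer(), exact = character(),
    provenance = character()
  )
  sents <- methods_sentences(document, section_classifier)
  if (is.null(sents) || nrow(sents) == 0) return(empty)

  tokenized <- purrr::map(seq_len(nrow(sents)), function(i) {
    list(
      doc_id = document$doc_id,
      sent_id = sents$sent_id[i],
      text = sents$text[i],
      tokens = wordpiece_tokenize(sents$text[i], vocab)
    )
  })
  feats <- purrr::map(tokenized, function(ts) featurize_tokens(ts$tokens))

  spans <- purrr::map(entity_types(), function(type) {
    lab <- labelers[[type]]
    ids <- purrr::map(feats, features_to_ids, index = lab$feature_index)
    pred <- .crf_viterbi(ids, lab$W, lab$trans, lab$start)
    decoded <- purrr::map(seq_along(tokenized), function(i) {
      ts <- tokenized[[i]]
      ts$tags <- ids_to_tags(pred[[i]])
      ts$entity_type <- type
      decode_spans(ts)
    })
    dplyr::bind_rows(decoded) |> distinct()
  })
  out <- dplyr::bind_rows(spans)
  if (nrow(out) == 0) return(empty)
  out |> mutate(provenance = "predicted")
}

#' Annotate every document in a corpus
#'
#' @param corpus A corpus tibble.
#' @param labelers Named list of `sequence_labeler` (one per schema type).
#' @param vocab A `wordpiece_vocab`.
#' @param section_classifier Optional section classifier fallback.
#' @return A tibble of predicted spans over the corpus.
#' @export
annotate_corpus <- function(corpus, labelers, vocab = fixture_vocab(),
                            section_classifier = NULL) {
  purrr::map(seq_len(nrow(corpus)), function(i) {
    annotate_document(corpus[i, ], labelers, vocab, section_classifier)
  }) |>
    dplyr::bind_rows()
}
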