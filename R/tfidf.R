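# TF-IDF document features on sparse matrices: lowercase, strip punctuation
# except within-token hyphens, unigram counts, smoothed inverse document
# frequency, L2-normalised rows.

tfidf_tokenize <- function(text) {
  x <- tolower(text)
  # keep letters, digits and within-token hyphens; everything else is a gap
  x <- gsub("[^a-z0-9-]+", " ", x)
  x <- gsub("(^|\\s)-+|-+(\\s|$)", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Fit a TF-IDF model
#'
#' Standard tf-idf weighting with smoothed idf,
#' `idf(t) = ln((1 + n_docs) / (1 + df(t))) + 1`, and L2-normalised rows.
#' Terms occurring in fewer than `min_count` documents are dropped
#' (default 2: hapax terms carry no class signal at this corpus scale).
#'
#' @param texts Character vector of documents (at least one non-empty).
#' @param min_count Minimum document frequency for a term to enter the
#'   vocabulary.
#' @return An object of class `tfidf_model` with fields `vocabulary`
#'   (term -> column index) and `idf`.
#' @export
fit_tfidf <- function(texts, min_count = 2) {
  token_lists <- lapply(texts, tfidf_tokenize)
  if (all(lengths(token_lists) == 0)) {
    stop("all documents are empty; cannot fit TF-IDF", call. = FALSE)
  }
  df <- table(unlist(lapply(token_lists, unique)))
  keep <- names(df)[df >= min_count]
  if (length(keep) == 0) {
    stop("vocabulary is empty after the min_count filter", call. = FALSE)
  }
  keep <- sort(keep)
  n_docs <- length(texts)
  dfv <- as.numeric(df[keep])
  idf <- log((1 + n_docs) / (1 + dfv)) + 1
  names(idf) <- keep
  structure(
    list(
      vocabulary = stats::setNames(seq_along(keep), keep),
      idf = idf,
      n_docs = n_docs
    ),
    class = "tfidf_model"
  )
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("<tfidf_model>", length(x$vocabulary), "terms over", x$n_docs,
      "documents\n")
  invisible(x)
}

#' Transform texts into TF-IDF vectors
#'
#' @param model A `tfidf_model`.
#' @param texts Character vector.
#' @return A sparse `dgCMatrix` with one L2-normalised row per text; texts
#'   with no in-vocabulary terms map to zero rows.
#' @export
tfidf_transform <- function(model, texts) {
  stopifnot(inherits(model, "tfidf_model"))
  vocab <- model$vocabulary
  triplets <- purrr::imap(texts, function(text, i) {
    toks <- tfidf_tokenize(text)
    toks <- toks[toks %in% names(vocab)]
    if (length(toks) == 0) return(NULL)
    tf <- table(toks)
    list(
      i = rep(i, length(tf)),
      j = unname(vocab[names(tf)]),
      x = as.numeric(tf) * unname(model$idf[names(tf)])
    )
  })
  triplets <- purrr::compact(triplets)
  m <- Matrix::sparseMatrix(
    i = unlist(purrr::map(triplets, "i")) %||% integer(0),
    j = unlist(purrr::map(triplets, "j")) %||% integer(0),
    x = unlist(purrr::map(triplets, "x")) %||% numeric(0),
    dims = c(length(texts), length(vocab)),
    dimnames = list(NULL, names(vocab))
  )
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  Matrix::Diagonal(x = 1 / norms) %*% m
}
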