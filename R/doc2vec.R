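# Paragraph vectors (distributed bag of words flavour): each document gets a
# dense vector trained to predict the words it contains, against negative
# samples drawn from the smoothed unigram distribution. Compact pure-R
# implementation sized for desk-scale corpora.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Fit paragraph-vector document embeddings
#'
#' Distributed-bag-of-words paragraph vectors with negative sampling. The
#' defaults mirror the established document-embedding recipe: 200
#' dimensions, 15 training epochs, window 5. The window parameter is stored
#' for interface compatibility but unused by the bag-of-words variant; the
#' `workers` parameter is a parallelism hint only (training here is
#' single-threaded, so any value yields the same result, and determinism
#' under a fixed seed always holds).
#'
#' @param texts Character vector of documents (at least two).
#' @param dim Embedding dimensionality.
#' @param window Context window size (stored; unused by the DBOW variant).
#' @param epochs Training passes over the corpus.
#' @param workers Parallelism hint (single-threaded implementation).
#' @param negative Number of negative samples per target word.
#' @param alpha Initial learning rate (linearly decayed).
#' @param seed Integer seed.
#' @return An object of class `doc2vec_model` with the trained document
#'   vectors in `$docvecs` (one row per input text).
#' @export
fit_doc_embeddings <- function(texts, dim = 200, window = 5, epochs = 15,
                               workers = 1, negative = 5, alpha = 0.05,
                               seed = 1) {
  if (dim <= 0) stop("embedding dimension must be positive", call. = FALSE)
  if (length(texts) < 2) stop("need at least 2 texts", call. = FALSE)
  token_lists <- lapply(texts, tfidf_tokenize)
  vocab <- sort(unique(unlist(token_lists)))
  if (length(vocab) == 0) stop("all documents are empty", call. = FALSE)
  freq <- table(factor(unlist(token_lists), levels = vocab))
  noise <- as.numeric(freq)^0.75
  noise <- noise / sum(noise)
  docs <- lapply(token_lists, function(t) match(t, vocab))

  with_local_seed(seed, {
    D <- matrix(stats::runif(length(texts) * dim, -0.5, 0.5) / dim,
                nrow = length(texts))
    W <- matrix(0, nrow = length(vocab), ncol = dim)
    total <- epochs * length(texts)
    step <- 0
    for (ep in seq_len(epochs)) {
      for (d in seq_along(docs)) {
        step <- step + 1
        lr <- alpha * max(1e-4, 1 - step / total)
        targets <- docs[[d]]
        if (length(targets) == 0) next
        negs <- sample.int(length(vocab), negative * length(targets),
                           replace = TRUE, prob = noise)
        v <- D[d, ]
        grad_v <- numeric(dim)
        # positive words
        scores <- sigmoid(W[targets, , drop = FALSE] %*% v)
        gpos <- as.numeric(scores - 1)
        grad_v <- grad_v + crossprod(W[targets, , drop = FALSE], gpos)[, 1]
        W[targets, ] <- W[targets, , drop = FALSE] -
          lr * gpos %o% v
        # negative samples
        nscores <- sigmoid(W[negs, , drop = FALSE] %*% v)
        gneg <- as.numeric(nscores)
        grad_v <- grad_v + crossprod(W[negs, , drop = FALSE], gneg)[, 1]
        W[negs, ] <- W[negs, , drop = FALSE] - lr * gneg %o% v
        D[d, ] <- v - lr * grad_v
      }
    }
    structure(
      list(
        docvecs = D, word_vectors = W, vocabulary = vocab, noise = noise,
        dim = dim, window = window, epochs = epochs, workers = workers,
        negative = negative, alpha = alpha, seed = seed
      ),
      class = "doc2vec_model"
    )
  })
}

#' @export
print.doc2vec_model <- function(x, ...) {
  cat("<doc2vec_model>", nrow(x$docvecs), "documents, dim", x$dim, "\n")
  invisible(x)
}

#' Infer a paragraph vector for new text
#'
#' Word vectors are held fixed; a fresh document vector is trained against
#' them for `epochs` passes.
#'
#' @param model A `doc2vec_model`.
#' @param texts Character vector.
#' @param epochs Inference passes.
#' @param seed Integer seed.
#' @return A matrix with `length(texts)` rows and `model$dim` columns.
#' @export
infer_docvec <- function(model, texts, epochs = model$epochs, seed = 1) {
  stopifnot(inherits(model, "doc2vec_model"))
  dim <- model$dim
  with_local_seed(seed, {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      toks <- tfidf_tokenize(texts[i])
      targets <- match(toks, model$vocabulary)
      targets <- targets[!is.na(targets)]
      v <- stats::runif(dim, -0.5, 0.5) / dim
      if (length(targets) > 0) {
        for (ep in seq_len(epochs)) {
          lr <- model$alpha * max(1e-4, 1 - ep / (epochs + 1))
          negs <- sample.int(length(model$vocabulary),
                             model$negative * length(targets),
                             replace = TRUE, prob = model$noise)
          gpos <- as.numeric(
            sigmoid(model$word_vectors[targets, , drop = FALSE] %*% v) - 1
          )
          gneg <- as.numeric(
            sigmoid(model$word_vectors[negs, , drop = FALSE] %*% v)
          )
          grad_v <-
            crossprod(model$word_vectors[targets, , drop = FALSE], gpos)[, 1] +
            crossprod(model$word_vectors[negs, , drop = FALSE], gneg)[, 1]
          v <- v - lr * grad_v
        }
      }
      out[i, ] <- v
    }
    out
  })
}
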