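# Modified WordPiece tokenization: greedy longest-match-first subword
# segmentation that PRESERVES unsegmentable words as single tokens (with a
# flag) instead of collapsing them to an unknown-token marker. Long primer
# strings, kit names, and chemical states with characters outside the
# vocabulary therefore stay visible to the sequence labelers.

#' Load a subword vocabulary
#'
#' One token per line; continuation pieces are prefixed with `##`; lines
#' bracketed like `[UNK]` are treated as special tokens. Matching is
#' case-insensitive (the vocabulary is case-folded on load) while token
#' offsets always refer to the original sentence text.
#'
#' @param path Path to a vocabulary file, or a character vector of tokens.
#' @return An object of class `wordpiece_vocab`.
#' @export
load_wordpiece_vocab <- function(path) {
  tokens <- if (length(path) == 1 && file.exists(path)) {
    readLines(path, warn = FALSE, encoding = "UTF-8")
  } else {
    as.character(path)
  }
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) stop("empty WordPiece vocabulary", call. = FALSE)
  special <- grepl("^\\[.*\\]$", tokens)
  pieces <- tolower(tokens[!special])
  env <- new.env(parent = emptyenv(), size = length(pieces) * 2L)
  for (p in pieces) assign(p, TRUE, envir = env)
  bare <- sub("^##", "", pieces)
  structure(
    list(
      pieces = env,
      n = length(pieces),
      special = tokens[special],
      max_piece = max(nchar(bare))
    ),
    class = "wordpiece_vocab"
  )
}

#' @export
print.wordpiece_vocab <- function(x, ...) {
  cat("<wordpiece_vocab>", x$n, "pieces,",
      length(x$special), "special tokens\n")
  invisible(x)
}

#' The fixture subword vocabulary shipped with the package
#'
#' A small vocabulary built from the synthetic generator's word lists plus
#' single-character and common-suffix pieces. It deliberately lacks the
#' prime and dash characters used in primer strings so the preserved-unknown
#' path is always exercised.
#'
#' @return A `wordpiece_vocab`.
#' @export
fixture_vocab <- function() {
  load_wordpiece_vocab(
    system.file("extdata", "wordpiece_vocab.txt", package = "metamine",
                mustWork = TRUE)
  )
}

has_piece <- function(vocab, piece) {
  exists(piece, envir = vocab$pieces, inherits = FALSE)
}

# Greedy longest-match segmentation of a single (case-folded) word.
# Returns integer vector of piece lengths, or NULL when the word cannot be
# fully segmented.
wordpiece_segment <- function(word, vocab) {
  n <- nchar(word)
  lens <- integer(0)
  pos <- 1L
  while (pos <= n) {
    remaining <- n - pos + 1L
    len <- min(remaining, vocab$max_piece)
    found <- 0L
    while (len >= 1L) {
      piece <- substr(word, pos, pos + len - 1L)
      key <- if (pos > 1L) paste0("##", piece) else piece
      if (has_piece(vocab, key)) {
        found <- len
        break
      }
      len <- len - 1L
    }
    if (found == 0L) return(NULL)
    lens <- c(lens, found)
    pos <- pos + found
  }
  lens
}

#' Tokenize a sentence with the modified WordPiece tokenizer
#'
#' Words are whitespace-pretokenized, then each word is segmented by greedy
#' longest-match-first lookup against the vocabulary. A word that cannot be
#' fully segmented is emitted as one token with `is_preserved_unknown =
#' TRUE`; no token ever carries an unknown-token marker. Character offsets
#' (0-based, half-open, relative to the sentence) are preserved for every
#' piece, so detokenization by offsets reproduces the sentence exactly.
#'
#' @param text Sentence text (single string).
#' @param vocab A `wordpiece_vocab`.
#' @return A tibble with columns `token_idx`, `text`, `char_start`,
#'   `char_end`, `is_continuation_piece`, `is_preserved_unknown`.
#' @export
wordpiece_tokenize <- function(text, vocab) {
  stopifnot(inherits(vocab, "wordpiece_vocab"),
            is.character(text), length(text) == 1)
  empty <- tibble::tibble(
    token_idx = integer(), text = character(),
    char_start = integer(), char_end = integer(),
    is_continuation_piece = logical(), is_preserved_unknown = logical()
  )
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  m <- gregexpr("\\S+", text)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  rows <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    word <- substr(text, starts[w], starts[w] + lens[w] - 1L)
    seg <- wordpiece_segment(tolower(word), vocab)
    if (is.null(seg)) {
      rows[[w]] <- tibble::tibble(
        text = word,
        char_start = starts[w] - 1L,
        char_end = starts[w] - 1L + lens[w],
        is_continuation_piece = FALSE,
        is_preserved_unknown = TRUE
      )
    } else {
      piece_end <- cumsum(seg)
      piece_start <- piece_end - seg
      rows[[w]] <- tibble::tibble(
        text = substring(word, piece_start + 1L, piece_end),
        char_start = starts[w] - 1L + piece_start,
        char_end = starts[w] - 1L + piece_end,
        is_continuation_piece = seq_along(seg) > 1L,
        is_preserved_unknown = FALSE
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$char_start <- as.integer(out$char_start)
  out$char_end <- as.integer(out$char_end)
  tibble::tibble(token_idx = seq_len(nrow(out)), out)
}

#' Reconstruct sentence text from token offsets
#'
#' @param tokens A token tibble from [wordpiece_tokenize()].
#' @param n_chars Total sentence length in characters (defaults to the last
#'   token's end).
#' @return The sentence text with inter-token gaps as single spaces.
#' @export
detokenize <- function(tokens, n_chars = NULL) {
  if (nrow(tokens) == 0) return("")
  if (is.null(n_chars)) n_chars <- max(tokens$char_end)
  chars <- rep(" ", n_chars)
  for (i in seq_len(nrow(tokens))) {
    piece <- strsplit(tokens$text[i], "", fixed = TRUE)[[1]]
    chars[(tokens$char_start[i] + 1):tokens$char_end[i]] <- piece
  }
  paste(chars, collapse = "")
}
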