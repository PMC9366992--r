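# Span annotations are anchored to sentences by exact text plus
# prefix/suffix context, sentences are tokenized with the modified
# WordPiece tokenizer, and one BIO dataset per entity type is emitted so
# nested/overlapping mentions of different types can be learned separately.

common_suffix_len <- function(a, b) {
  # longest suffix of `a` that is a suffix of `b`
  n <- min(nchar(a), nchar(b))
  k <- 0
  while (k < n &&
         substr(a, nchar(a) - k, nchar(a) - k) ==
         substr(b, nchar(b) - k, nchar(b) - k)) {
    k <- k + 1
  }
  k
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  k <- 0
  while (k < n && substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1)) {
    k <- k + 1
  }
  k
}

str_locate_all_fixed <- function(text, pattern) {
  out <- integer(0)
  start <- 1L
  repeat {
    hit <- regexpr(pattern, substring(text, start), fixed = TRUE)
    if (hit == -1) break
    out <- c(out, start + as.integer(hit) - 1L)
    start <- start + as.integer(hit) + max(1L, attr(hit, "match.length")) - 1L
  }
  out
}

#' Anchor raw annotations to corpus sentences
#'
#' Each raw annotation carries the exact mention text plus prefix/suffix
#' context. Occurrences of the exact text are located in the document's
#' sentences; multiple occurrences are disambiguated by the longest
#' suffix-of-prefix / prefix-of-suffix context match. Unanchorable or
#' still-ambiguous annotations are collected in a rejects report.
#'
#' @param corpus A corpus tibble.
#' @param raw A tibble with columns `doc_id`, `exact`, `prefix`, `suffix`,
#'   `entity_type` (and optionally `provenance`).
#' @return A list with `anchored` (tibble with `sent_id` and
#'   sentence-relative `char_start`/`char_end`, slice equals `exact`) and
#'   `rejects` (tibble with a `reason` column: `"unanchorable"` or
#'   `"ambiguous"`).
#' @export
anchor_annotations <- function(corpus, raw) {
  check_entity_type(raw$entity_type)
  sents <- corpus_sentences(corpus)
  if (!"provenance" %in% names(raw)) raw$provenance <- "curated"
  anchored <- list()
  rejects <- list()
  sents_by_doc <- split(sents, sents$doc_id)
  for (i in seq_len(nrow(raw))) {
    ann <- raw[i, ]
    if (!nzchar(ann$exact)) {
      rejects[[length(rejects) + 1]] <- mutate(ann, reason = "empty exact")
      next
    }
    doc_sents <- sents_by_doc[[ann$doc_id]]
    cands <- NULL
    if (!is.null(doc_sents)) {
      cands <- purrr::map(seq_len(nrow(doc_sents)), function(s) {
        starts <- str_locate_all_fixed(doc_sents$text[s], ann$exact)
        if (length(starts) == 0) return(NULL)
        tibble::tibble(
          sent_id = doc_sents$sent_id[s],
          sent_text = doc_sents$text[s],
          char_start = starts - 1L
        )
      }) |>
        purrr::compact() |>
        dplyr::bind_rows()
    }
    if (is.null(cands) || nrow(cands) == 0) {
      rejects[[length(rejects) + 1]] <- mutate(ann, reason = "unanchorable")
      next
    }
    cands$char_end <- cands$char_start + nchar(ann$exact)
    if (nrow(cands) > 1) {
      pre <- if (is.na(ann$prefix)) "" else ann$prefix
      suf <- if (is.na(ann$suffix)) "" else ann$suffix
      score <- purrr::map_int(seq_len(nrow(cands)), function(k) {
        before <- substr(cands$sent_text[k], 1, cands$char_start[k])
        after <- substring(cands$sent_text[k], cands$char_end[k] + 1)
        common_suffix_len(pre, before) + common_prefix_len(suf, after)
      })
      top <- which(score == max(score))
      if (length(top) > 1) {
        rejects[[length(rejects) + 1]] <- mutate(ann, reason = "ambiguous")
        next
      }
      cands <- cands[top, ]
    }
    anchored[[length(anchored) + 1]] <- tibble::tibble(
      doc_id = ann$doc_id,
      sent_id = cands$sent_id,
      entity_type = ann$entity_type,
      char_start = as.integer(cands$char_start),
      char_end = as.integer(cands$char_end),
      exact = ann$exact,
      prefix = ann$prefix,
      suffix = ann$suffix,
      provenance = ann$provenance
    )
  }
  empty_anchor <- tibble::tibble(
    doc_id = character(), sent_id = character(), entity_type = character(),
    char_start = integer(), char_end = integer(), exact = character(),
    prefix = character(), suffix = character(), provenance = character()
  )
  list(
    anchored = if (length(anchored)) dplyr::bind_rows(anchored) else
      empty_anchor,
    rejects = if (length(rejects)) dplyr::bind_rows(rejects) else
      mutate(raw[0, ], reason = character(0))
  )
}

#' BIO-tag a tokenized sentence against spans of one entity type
#'
#' A token belongs to a span iff its character range overlaps the span's;
#' the first token of each span is tagged `B`, subsequent tokens `I`, all
#' others `O`. Adjacent distinct spans each restart at `B`.
#'
#' @param tokens A token tibble from [wordpiece_tokenize()].
#' @param spans A tibble with `char_start`, `char_end`, `entity_type`
#'   (sentence-relative offsets, all one type).
#' @return Character vector of tags, one per token.
#' @export
bio_tag <- function(tokens, spans) {
  if (nrow(spans) > 1 && length(unique(spans$entity_type)) > 1) {
    stop("bio_tag expects spans of a single entity type", call. = FALSE)
  }
  tags <- rep("O", nrow(tokens))
  if (nrow(spans) == 0 || nrow(tokens) == 0) return(tags)
  spans <- spans |> arrange(.data$char_start)
  for (s in seq_len(nrow(spans))) {
    inside <- which(tokens$char_start < spans$char_end[s] &
                      tokens$char_end > spans$char_start[s])
    if (length(inside) == 0) next
    tags[inside[1]] <- "B"
    if (length(inside) > 1) tags[inside[-1]] <- "I"
  }
  tags
}

#' Truncate a tagged sentence to a maximum token length
#'
#' @param tagged A tagged sentence: list with `tokens` and `tags`.
#' @param max_len Maximum number of tokens to keep.
#' @return The tagged sentence with `truncated` flag and
#'   `dropped_spans` count (gold spans starting beyond the cut are
#'   unlearnable and counted here).
#' @export
truncate_to_max_len <- function(tagged, max_len = 128) {
  stopifnot(max_len >= 1)
  n <- nrow(tagged$tokens)
  if (n <= max_len) {
    tagged$truncated <- FALSE
    tagged$dropped_spans <- 0L
    return(tagged)
  }
  dropped <- sum(tagged$tags[(max_len + 1):n] == "B")
  tagged$tokens <- tagged$tokens[seq_len(max_len), , drop = FALSE]
  tagged$tags <- tagged$tags[seq_len(max_len)]
  tagged$truncated <- TRUE
  tagged$dropped_spans <- as.integer(dropped)
  tagged
}

#' Build the 16 per-entity BIO datasets
#'
#' Tokenizes the curated sentences once, tags them per entity type (all-O
#' when the type is absent from a sentence), truncates to `max_len`, and
#' draws ONE 90/10 sentence split reused by all 16 datasets so no sentence
#' leaks between train and test across entity models.
#'
#' @param corpus A corpus tibble.
#' @param annotations Anchored annotation tibble (see
#'   [anchor_annotations()]).
#' @param vocab A `wordpiece_vocab`.
#' @param seed Integer seed for the sentence split.
#' @param max_len Maximum tokens per sentence.
#' @param train_frac Training fraction of the sentence split.
#' @param only_annotated If `TRUE` (default) the sentence universe is the
#'   entity-bearing sentences; otherwise every corpus sentence.
#' @return An object of class `entity_datasets`: a named list of per-type
#'   datasets, each with `entity_type`, `train`, `test` (lists of tagged
#'   sentences), and `max_len`. The shared split and the truncation log are
#'   attached as attributes.
#' @export
build_entity_datasets <- function(corpus, annotations, vocab = fixture_vocab(),
                                  seed = 9, max_len = 128, train_frac = 0.9,
                                  only_annotated = TRUE) {
  check_entity_type(annotations$entity_type)
  sents <- corpus_sentences(corpus)
  if (only_annotated) {
    sents <- sents |> filter(.data$sent_id %in% annotations$sent_id)
  }
  if (nrow(sents) == 0) stop("no sentences to build datasets from",
                             call. = FALSE)

  tokenized <- purrr::map(seq_len(nrow(sents)), function(i) {
    list(
      sent_id = sents$sent_id[i],
      doc_id = sents$doc_id[i],
      text = sents$text[i],
      tokens = wordpiece_tokenize(sents$text[i], vocab)
    )
  })
  names(tokenized) <- sents$sent_id

  if (train_frac >= 1) {
    split_tbl <- tibble::tibble(sent_id = sents$sent_id, split = "train")
  } else {
    sp <- split_train_test(tibble::tibble(sent_id = sents$sent_id),
                           train_frac = train_frac, seed = seed,
                           stratify_by = NULL)
    split_tbl <- dplyr::bind_rows(
      tibble::tibble(sent_id = sp$train$sent_id, split = "train"),
      tibble::tibble(sent_id = sp$test$sent_id, split = "test")
    )
  }

  ann_by <- split(annotations,
                  list(annotations$sent_id, annotations$entity_type),
                  drop = TRUE)
  truncation_log <- list()

  datasets <- purrr::map(entity_types(), function(type) {
    tagged <- purrr::map(tokenized, function(ts) {
      key <- paste(ts$sent_id, type, sep = ".")
      spans <- ann_by[[key]]
      if (is.null(spans)) {
        spans <- tibble::tibble(char_start = integer(), char_end = integer(),
                                entity_type = character())
      }
      out <- list(
        sent_id = ts$sent_id, doc_id = ts$doc_id, text = ts$text,
        entity_type = type, tokens = ts$tokens,
        tags = bio_tag(ts$tokens, spans)
      )
      truncate_to_max_len(out, max_len)
    })
    dropped <- sum(purrr::map_int(tagged, "dropped_spans"))
    if (dropped > 0) {
      truncation_log[[type]] <<- dropped
    }
    is_train <- split_tbl$split[match(names(tagged), split_tbl$sent_id)] ==
      "train"
    structure(
      list(
        entity_type = type,
        train = tagged[is_train],
        test = tagged[!is_train],
        max_len = max_len
      ),
      class = "entity_dataset"
    )
  })
  names(datasets) <- entity_types()
  structure(
    datasets,
    split = split_tbl,
    truncation_log = truncation_log,
    class = "entity_datasets"
  )
}

#' @export
print.entity_dataset <- function(x, ...) {
  cat("<entity_dataset>", x$entity_type, ":", length(x$train), "train /",
      length(x$test), "test sentences\n")
  invisible(x)
}

#' @export
print.entity_datasets <- function(x, ...) {
  cat("<entity_datasets>", length(x), "entity types;",
      length(x[[1]]$train), "train /", length(x[[1]]$test),
      "test sentences each\n")
  invisible(x)
}

#' Write entity datasets as per-type train/test TSV files
#'
#' @param datasets An `entity_datasets` object.
#' @param dir Output directory; one sub-directory per entity type with
#'   `train.tsv` / `test.tsv` (columns `sent_id`, `token`, `char_start`,
#'   `char_end`, `tag`).
#' @return `dir`, invisibly.
#' @export
write_entity_datasets <- function(datasets, dir) {
  for (type in names(datasets)) {
    d <- file.path(dir, gsub("[^A-Za-z0-9-]", "_", type))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    for (part in c("train", "test")) {
      rows <- purrr::map(datasets[[type]][[part]], function(ts) {
        tibble::tibble(
          sent_id = ts$sent_id,
          token = ts$tokens$text,
          char_start = ts$tokens$char_start,
          char_end = ts$tokens$char_end,
          tag = ts$tags
        )
      }) |>
        dplyr::bind_rows()
      utils::write.table(rows, file.path(d, paste0(part, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}
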