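#' @useDynLib metamine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# A corpus is a nested tibble: one row per document with columns
#   doc_id, source_id, title, sections (list of tibbles).
# Each sections tibble has columns heading, canonical_type, sentences
# (list of tibbles with sent_id, text, char_start, char_end).
# Offsets are 0-based, half-open, code-point indexed, relative to the
# whitespace-normalised section text.

#' Canonical section types
#'
#' The five canonical article section types plus the fallback `"other"`.
#'
#' @return Character vector of canonical section type names.
#' @export
canonical_section_types <- function() {
  c("abstract", "introduction", "methods", "results", "discussion", "other")
}

#' Default heading synonym table
#'
#' Maps raw (case-folded) section headings to canonical section types.
#' Users may extend it and pass the result to [read_jats()].
#'
#' @return A tibble with columns `heading` and `canonical_type`.
#' @export
section_synonyms <- function() {
  tibble::tribble(
    ~heading,                    ~canonical_type,
    "abstract",                  "abstract",
    "summary",                   "abstract",
    "introduction",              "introduction",
    "background",                "introduction",
    "methods",                   "methods",
    "method",                    "methods",
    "materials and methods",     "methods",
    "material and methods",      "methods",
    "methods and materials",     "methods",
    "experimental procedures",   "methods",
    "results",                   "results",
    "results and discussion",    "results",
    "findings",                  "results",
    "discussion",                "discussion",
    "conclusions",               "discussion",
    "conclusion",                "discussion"
  )
}

#' Assign a canonical section type to a heading
#'
#' Matching is case-insensitive and ignores surrounding whitespace and
#' trailing punctuation; unmatched headings map to `"other"`.
#'
#' @param heading Character vector of raw headings.
#' @param synonyms Synonym table as from [section_synonyms()].
#' @return Character vector of canonical types.
#' @export
canonical_section_type <- function(heading, synonyms = section_synonyms()) {
  key <- tolower(trimws(gsub("[[:punct:]]+$", "", trimws(heading))))
  out <- synonyms$canonical_type[match(key, synonyms$heading)]
  out[is.na(out)] <- "other"
  out
}

normalize_ws <- function(text) {
  trimws(gsub("\\s+", " ", text))
}

# Abbreviations that do not end a sentence when followed by a period.
sentence_guard_list <- function() {
  c("al", "e.g", "i.e", "fig", "figs", "sp", "spp", "cf", "ca",
    "approx", "vs", "etc", "no", "dr", "st")
}

#' Segment text into sentences
#'
#' Terminator-based sentence splitting with an abbreviation guard list.
#' Whitespace runs are collapsed to single spaces before segmentation, so
#' the returned offsets index the normalised text.
#'
#' @param text A single character string.
#' @return A tibble with columns `text`, `char_start`, `char_end`
#'   (0-based, half-open, code-point offsets into the normalised text).
#'   Sentence spans are ordered, non-overlapping, and cover every
#'   non-whitespace character.
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  norm <- normalize_ws(text)
  empty <- tibble(text = character(), char_start = integer(), char_end = integer())
  if (is.na(norm) || !nzchar(norm)) return(empty)

  chars <- strsplit(norm, "", fixed = TRUE)[[1]]
  n <- length(chars)
  guards <- sentence_guard_list()
  boundaries <- integer(0) # index (1-based) of the last char of a sentence
  for (i in seq_len(n)) {
    if (!chars[i] %in% c(".", "!", "?")) next
    if (i == n) next
    # terminator must be followed by a space and a plausible sentence opener
    if (chars[i + 1] != " ") next
    if (i + 2 > n) next
    opener <- chars[i + 2]
    if (!grepl("[A-Z0-9(\"']", opener)) next
    # guard: abbreviation or single-letter token before the period
    if (chars[i] == ".") {
      j <- i - 1
      while (j >= 1 && chars[j] != " ") j <- j - 1
      tok <- paste(chars[(j + 1):(i - 1)], collapse = "")
      if (nchar(tok) == 1 && grepl("[A-Za-z]", tok)) next
      if (tolower(tok) %in% guards) next
    }
    boundaries <- c(boundaries, i)
  }
  ends <- c(boundaries, n)
  starts <- c(1L, boundaries + 2L) # skip the single separating space
  texts <- substring(norm, starts, ends)
  tibble(
    text = texts,
    char_start = as.integer(starts - 1L),
    char_end = as.integer(ends)
  )
}

sentence_ids <- function(doc_id, section_idx, n) {
  if (n == 0) return(character(0))
  sprintf("%s:s%d:%d", doc_id, section_idx, seq_len(n))
}

#' Construct a one-document corpus tibble
#'
#' @param doc_id Document identifier, unique within a corpus.
#' @param source_id External identifier (e.g. a PMC accession); may be `NA`.
#' @param title Article title.
#' @param sections A tibble with columns `heading`, `canonical_type`,
#'   `sentences` (list of sentence tibbles), or `NULL` for a sectionless
#'   document.
#' @return A one-row corpus tibble.
#' @export
new_document <- function(doc_id, source_id = NA_character_, title = "",
                         sections = NULL) {
  if (is.null(sections)) {
    sections <- tibble(
      heading = character(), canonical_type = character(),
      sentences = list()
    )
  }
  tibble(
    doc_id = as.character(doc_id),
    source_id = as.character(source_id),
    title = as.character(title),
    sections = list(sections)
  )
}

make_section <- function(doc_id, section_idx, heading, text,
                         synonyms = section_synonyms()) {
  sents <- segment_sentences(text)
  sents <- tibble(
    sent_id = sentence_ids(doc_id, section_idx, nrow(sents)),
    text = sents$text,
    char_start = sents$char_start,
    char_end = sents$char_end
  )
  tibble(
    heading = heading,
    canonical_type = canonical_section_type(heading, synonyms),
    sentences = list(sents)
  )
}

#' Read a JATS-like article XML into a document
#'
#' Parses the JATS-like subset (`article`, `front/title`, `body`, `sec`,
#' `title`, `p`). Nested sub-sections are flattened into their top-level
#' parent; paragraph texts are concatenated, whitespace-normalised, and
#' sentence-segmented. Section types are assigned from the heading synonym
#' table, defaulting to `"other"`.
#'
#' @param xml Path to an XML file, an XML string, or raw bytes.
#' @param doc_id Optional document id; defaults to the `article` element's
#'   `id` attribute, falling back to the file name.
#' @param synonyms Heading synonym table, see [section_synonyms()].
#' @return A one-row corpus tibble. An article with an empty body yields a
#'   document with zero sections.
#' @export
read_jats <- function(xml, doc_id = NULL, synonyms = section_synonyms()) {
  is_path <- is.character(xml) && length(xml) == 1 && !grepl("<", xml) &&
    file.exists(xml)
  node <- tryCatch(
    xml2::read_xml(xml),
    error = function(e) {
      stop("malformed XML", if (is_path) paste0(" in ", xml), ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(doc_id)) {
    doc_id <- xml2::xml_attr(node, "id")
    if (is.na(doc_id) && is_path) {
      doc_id <- sub("\\.xml$", "", basename(xml))
    }
    if (is.na(doc_id)) doc_id <- "doc"
  }
  source_id <- xml2::xml_attr(node, "source-id")
  if (is.na(source_id)) {
    sid <- xml2::xml_find_first(node, "./front/article-id")
    if (!inherits(sid, "xml_missing")) source_id <- xml2::xml_text(sid)
  }
  title_node <- xml2::xml_find_first(node, "./front/title")
  title <- if (inherits(title_node, "xml_missing")) "" else
    normalize_ws(xml2::xml_text(title_node))

  secs <- xml2::xml_find_all(node, "./body/sec")
  if (length(secs) == 0) {
    return(new_document(doc_id, source_id, title))
  }
  sections <- purrr::imap(secs, function(sec, i) {
    title_el <- xml2::xml_find_first(sec, "./title")
    heading <- if (inherits(title_el, "xml_missing")) "" else
      normalize_ws(xml2::xml_text(title_el))
    paras <- xml2::xml_find_all(sec, ".//p")
    text <- normalize_ws(paste(xml2::xml_text(paras), collapse = " "))
    make_section(doc_id, i, heading, text, synonyms)
  })
  new_document(doc_id, source_id, title, dplyr::bind_rows(sections))
}

#' Write a document as JATS-like XML
#'
#' Inverse of [read_jats()] on the JATS-like dialect: section texts are
#' reconstructed from the stored sentence offsets.
#'
#' @param document A one-row corpus tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jats <- function(document, path) {
  stopifnot(nrow(document) == 1)
  root <- xml2::xml_new_root("article")
  xml2::xml_set_attr(root, "id", document$doc_id)
  if (!is.na(document$source_id)) {
    xml2::xml_set_attr(root, "source-id", document$source_id)
  }
  front <- xml2::xml_add_child(root, "front")
  xml2::xml_add_child(front, "title", document$title)
  body <- xml2::xml_add_child(root, "body")
  secs <- document$sections[[1]]
  for (i in seq_len(nrow(secs))) {
    sec <- xml2::xml_add_child(body, "sec")
    if (nzchar(secs$heading[i])) {
      xml2::xml_add_child(sec, "title", secs$heading[i])
    }
    xml2::xml_add_child(sec, "p", section_text(secs$sentences[[i]]))
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Reconstruct a section's text from its sentences
#'
#' Places each sentence at its recorded offset; inter-sentence gaps are
#' single spaces by the whitespace-normalisation contract.
#'
#' @param sentences A sentence tibble (`sent_id`, `text`, `char_start`,
#'   `char_end`).
#' @return The section text as a single string (empty for zero sentences).
#' @export
section_text <- function(sentences) {
  if (nrow(sentences) == 0) return("")
  total <- max(sentences$char_end)
  chars <- rep(" ", total)
  for (i in seq_len(nrow(sentences))) {
    piece <- strsplit(sentences$text[i], "", fixed = TRUE)[[1]]
    chars[(sentences$char_start[i] + 1):sentences$char_end[i]] <- piece
  }
  paste(chars, collapse = "")
}

#' Flatten a corpus to one row per sentence
#'
#' @param corpus A corpus tibble.
#' @return A tibble with columns `doc_id`, `source_id`, `title`,
#'   `section_idx`, `heading`, `canonical_type`, `sent_id`, `text`,
#'   `char_start`, `char_end`.
#' @export
corpus_sentences <- function(corpus) {
  if (nrow(corpus) == 0) {
    return(tibble(
      doc_id = character(), source_id = character(), title = character(),
      section_idx = integer(), heading = character(),
      canonical_type = character(), sent_id = character(), text = character(),
      char_start = integer(), char_end = integer()
    ))
  }
  corpus |>
    tidyr::unnest("sections") |>
    group_by(.data$doc_id) |>
    mutate(section_idx = row_number()) |>
    ungroup() |>
    tidyr::unnest("sentences") |>
    select("doc_id", "source_id", "title", "section_idx", "heading",
           "canonical_type", "sent_id", "text", "char_start", "char_end")
}

#' Concatenate a document's text for a given scope
#'
#' @param document A one-row corpus tibble.
#' @param scope One of the canonical section types or `"fulltext"`.
#' @return A single string (empty when no section matches).
#' @export
document_text <- function(document, scope = "fulltext") {
  stopifnot(scope %in% c(canonical_section_types(), "fulltext"))
  secs <- document$sections[[1]]
  if (nrow(secs) == 0) return("")
  keep <- if (scope == "fulltext") rep(TRUE, nrow(secs)) else
    secs$canonical_type == scope
  texts <- purrr::map_chr(secs$sentences[keep], section_text)
  paste(texts[nzchar(texts)], collapse = " ")
}

doc_to_list <- function(row) {
  secs <- row$sections[[1]]
  list(
    doc_id = row$doc_id,
    source_id = if (is.na(row$source_id)) NULL else row$source_id,
    title = row$title,
    sections = purrr::map(seq_len(nrow(secs)), function(i) {
      s <- secs$sentences[[i]]
      list(
        heading = secs$heading[i],
        canonical_type = secs$canonical_type[i],
        sentences = purrr::map(seq_len(nrow(s)), function(j) {
          list(
            sent_id = s$sent_id[j], text = s$text[j],
            char_start = s$char_start[j], char_end = s$char_end[j]
          )
        })
      )
    })
  )
}

doc_from_list <- function(x) {
  sections <- purrr::map(x$sections, function(sec) {
    sents <- purrr::map(sec$sentences, function(s) {
      tibble(
        sent_id = as.character(s$sent_id), text = as.character(s$text),
        char_start = as.integer(s$char_start), char_end = as.integer(s$char_end)
      )
    })
    sents <- if (length(sents)) dplyr::bind_rows(sents) else
      tibble(sent_id = character(), text = character(),
             char_start = integer(), char_end = integer())
    tibble(
      heading = as.character(sec$heading),
      canonical_type = as.character(sec$canonical_type),
      sentences = list(sents)
    )
  })
  sections <- if (length(sections)) dplyr::bind_rows(sections) else NULL
  new_document(
    x$doc_id,
    if (is.null(x$source_id)) NA_character_ else x$source_id,
    x$title, sections
  )
}

#' Write a corpus as JSONL
#'
#' One JSON object per line with keys `doc_id`, `source_id`, `title`,
#' `sections[{heading, canonical_type, sentences[{sent_id, text,
#' char_start, char_end}]}]`.
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- purrr::map_chr(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(doc_to_list(corpus[i, ]), auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from JSONL
#'
#' Inverse of [write_corpus_jsonl()]; a malformed line raises an error
#' naming its line number.
#'
#' @param path Input file path.
#' @return A corpus tibble (zero rows for an empty file).
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(new_document(character(0))[0, ])
  docs <- purrr::imap(lines, function(line, i) {
    x <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = FALSE),
      error = function(e) {
        stop("malformed JSONL at line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    doc_from_list(x)
  })
  dplyr::bind_rows(docs)
}
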