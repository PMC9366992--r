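# Distant supervision: biome lineage labels recorded on study records are
# projected onto the publications the studies cross-reference, yielding
# labeled texts without hand-labeling. Documents whose studies disagree at
# the requested lineage level are dropped (and reported) rather than kept
# with noisy labels.

#' Project study biome labels onto cross-referenced documents
#'
#' @param studies A tibble with columns `study_id`, `biome_lineage`
#'   (list-column of ordered character vectors, levels 1..5), and
#'   `publication_ids` (list-column of doc ids).
#' @param corpus A corpus tibble.
#' @param level Lineage level to label at, 1..5.
#' @param scope One of the canonical section types or `"fulltext"`: the text
#'   extracted per document.
#' @return A tibble of labeled texts with columns `doc_id`, `scope`, `text`,
#'   `label`. Documents referenced by studies that conflict at `level` are
#'   dropped; their ids are attached as the `"conflicts"` attribute.
#'   Documents with no text in scope are skipped.
#' @export
map_labels <- function(studies, corpus, level = 1, scope = "fulltext") {
  stopifnot(level >= 1, level <= 5)
  stopifnot(scope %in% c(canonical_section_types(), "fulltext"))

  pairs <- studies |>
    mutate(label = purrr::map_chr(.data$biome_lineage, function(lin) {
      if (length(lin) >= level) lin[[level]] else NA_character_
    })) |>
    filter(!is.na(.data$label)) |>
    select("study_id", "label", "publication_ids") |>
    tidyr::unnest_longer("publication_ids", values_to = "doc_id")

  if (nrow(pairs) == 0) {
    warning("no study lineage reaches level ", level, call. = FALSE)
    return(structure(
      tibble::tibble(doc_id = character(), scope = character(),
                     text = character(), label = character()),
      conflicts = character(0)
    ))
  }

  per_doc <- pairs |>
    distinct(.data$doc_id, .data$label) |>
    count(.data$doc_id, name = "n_labels")
  conflicted <- per_doc$doc_id[per_doc$n_labels > 1]
  if (length(conflicted) > 0) {
    message("dropping ", length(conflicted),
            " document(s) with conflicting labels at level ", level)
  }
  clean <- pairs |>
    filter(!.data$doc_id %in% conflicted) |>
    distinct(.data$doc_id, .data$label)

  texts <- corpus |>
    filter(.data$doc_id %in% clean$doc_id)
  out <- purrr::map(seq_len(nrow(texts)), function(i) {
    tibble::tibble(
      doc_id = texts$doc_id[i],
      scope = scope,
      text = document_text(texts[i, ], scope)
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(doc_id = character(), scope = character(),
                          text = character())
  }
  out <- out |>
    filter(nzchar(.data$text)) |>
    inner_join(clean, by = "doc_id") |>
    rename(label = "label")
  structure(out, conflicts = conflicted)
}

#' Balance a labeled dataset by class
#'
#' Classes with fewer than `min_per_class` examples are excluded; every
#' retained class is downsampled without replacement to
#' `k = min(max_per_class, smallest retained class size)`, so retained
#' classes end up exactly equal in size.
#'
#' @param labeled A tibble with a `label` column.
#' @param min_per_class Minimum examples for a class to be retained.
#' @param max_per_class Cap on examples per retained class.
#' @param seed Integer seed for the downsampling draw.
#' @return The balanced tibble; excluded classes are attached as the
#'   `"excluded"` attribute.
#' @export
balance_dataset <- function(labeled, min_per_class = 20, max_per_class = 100,
                            seed = 1) {
  stopifnot(min_per_class <= max_per_class)
  counts <- labeled |> count(.data$label, name = "n")
  excluded <- counts$label[counts$n < min_per_class]
  retained <- counts |> filter(.data$n >= min_per_class)
  if (length(excluded) > 0) {
    message("excluding ", length(excluded), " class(es) below min_per_class: ",
            paste(excluded, collapse = ", "))
  }
  if (nrow(retained) < 2) {
    stop("fewer than 2 classes retained; cannot train a multiclass model",
         call. = FALSE)
  }
  k <- min(max_per_class, min(retained$n))
  out <- with_local_seed(seed, {
    labeled |>
      filter(.data$label %in% retained$label) |>
      group_by(.data$label) |>
      slice_sample(n = k) |>
      ungroup()
  })
  structure(out, excluded = excluded)
}

#' Stratified train/test split with the floor rule
#'
#' Per stratum, the training size is `floor(train_frac * stratum size)`;
#' the remainder goes to test. A stratum of size 1 is placed in train with
#' a warning. The split is a partition: disjoint and exhaustive.
#'
#' @param items A tibble (or data frame) of items.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratify_by If non-`NULL`, the column name to stratify by
#'   (typically `"label"`); `NULL` treats all items as one stratum.
#' @return A list with elements `train` and `test`.
#' @export
split_train_test <- function(items, train_frac = 0.8, seed = 1,
                             stratify_by = "label") {
  stopifnot(train_frac > 0, train_frac < 1)
  n <- nrow(items)
  strata <- if (is.null(stratify_by)) rep("all", n) else items[[stratify_by]]
  idx_train <- with_local_seed(seed, {
    unlist(lapply(split(seq_len(n), strata), function(idx) {
      m <- length(idx)
      if (m == 1) {
        warning("stratum of size 1 placed in train", call. = FALSE)
        return(idx)
      }
      k <- floor(train_frac * m)
      sample(idx, k)
    }), use.names = FALSE)
  })
  list(
    train = items[sort(idx_train), , drop = FALSE],
    test = items[setdiff(seq_len(n), sort(idx_train)), , drop = FALSE]
  )
}
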