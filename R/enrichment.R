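# Database enrichment: publication-derived annotations are emitted as
# Europe PMC-style annotation records (with a pluggable dictionary-backed
# ontology mapper), study XML is parsed for accession links, both sources
# are mapped onto the MIxS checklist, and per-study/per-term cells are
# compared as identical / nonidentical / unique-to-source.

#' Dictionary-backed ontology mapper
#'
#' The normalization contract: a pure lookup from (surface term, entity
#' type) to an ontology tag. Unmapped terms return no tag, never an error.
#' Web-service mappers can implement the same contract.
#'
#' @param dictionary A tibble with columns `term`, `entity_type`, `name`,
#'   `uri`.
#' @return An object of class `ontology_mapper`.
#' @export
dictionary_mapper <- function(dictionary = NULL) {
  if (is.null(dictionary)) {
    dictionary <- tibble::tibble(
      term = character(), entity_type = character(),
      name = character(), uri = character()
    )
  }
  stopifnot(all(c("term", "entity_type", "name", "uri") %in%
                  names(dictionary)))
  dictionary$term <- tolower(dictionary$term)
  structure(list(dictionary = dictionary), class = "ontology_mapper")
}

#' Look up an ontology tag for a term
#'
#' @param mapper An `ontology_mapper`.
#' @param term Surface text of the mention.
#' @param entity_type The mention's entity type.
#' @return A one-row tibble with `name` and `uri`, or `NULL` when unmapped.
#' @export
map_term <- function(mapper, term, entity_type) {
  stopifnot(inherits(mapper, "ontology_mapper"))
  hit <- mapper$dictionary |>
    filter(.data$term == tolower(!!term),
           .data$entity_type == !!entity_type)
  if (nrow(hit) == 0) return(NULL)
  hit[1, c("name", "uri")]
}

#' Emit an annotation record for a document
#'
#' One annotation per predicted span, with `exact` the span text and
#' `prefix`/`postfix` up to 30 characters of surrounding sentence text.
#' Ontology tags come from the mapper and are omitted when unmapped. The
#' record integrity-checks every span against the document text.
#'
#' @param document A one-row corpus tibble.
#' @param spans Predicted span tibble for the document (`sent_id`,
#'   `entity_type`, `char_start`, `char_end`, `exact`).
#' @param mapper An `ontology_mapper` (default: empty dictionary).
#' @param provider Provider name recorded on the record.
#' @param collection Source collection id.
#' @return An object of class `annotation_record`.
#' @export
emit_annotations <- function(document, spans, mapper = dictionary_mapper(),
                             provider = "metamine",
                             collection = "metagenomics") {
  stopifnot(nrow(document) == 1)
  sents <- corpus_sentences(document)
  anns <- purrr::map(seq_len(nrow(spans)), function(i) {
    sp <- spans[i, ]
    s <- sents[sents$sent_id == sp$sent_id, ]
    if (nrow(s) != 1) {
      stop("span references unknown sentence ", sp$sent_id, call. = FALSE)
    }
    slice <- substring(s$text, sp$char_start + 1, sp$char_end)
    if (!identical(slice, sp$exact)) {
      stop("span integrity error in ", document$doc_id, ": '", slice,
           "' != '", sp$exact, "'", call. = FALSE)
    }
    section_label <- s$canonical_type
    ann <- list(
      exact = sp$exact,
      prefix = clip_context(substr(s$text, 1, sp$char_start), 30),
      postfix = substr(s$text, sp$char_end + 1, sp$char_end + 30),
      section = section_label,
      entity_type = sp$entity_type,
      tags = list()
    )
    tag <- map_term(mapper, sp$exact, sp$entity_type)
    if (!is.null(tag)) {
      ann$tags <- list(list(name = tag$name, uri = tag$uri))
    }
    ann
  })
  structure(
    list(
      collection = collection,
      article_id = if (!is.na(document$source_id)) document$source_id else
        document$doc_id,
      provider = provider,
      annotations = anns
    ),
    class = "annotation_record"
  )
}

#' @export
print.annotation_record <- function(x, ...) {
  cat("<annotation_record>", x$article_id, "from", x$provider, "with",
      length(x$annotations), "annotations\n")
  invisible(x)
}

sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
    x <- x[order(names(x))]
    lapply(x, sort_keys)
  } else if (is.list(x)) {
    lapply(x, sort_keys)
  } else {
    x
  }
}

#' Serialize an annotation record as stable JSON
#'
#' Keys are sorted so serialization is byte-stable.
#'
#' @param record An `annotation_record`.
#' @return A JSON string.
#' @export
annotation_record_json <- function(record) {
  as.character(jsonlite::toJSON(sort_keys(unclass(record)),
                                auto_unbox = TRUE, digits = NA))
}

#' Parse an annotation record from JSON
#'
#' @param json A JSON string produced by [annotation_record_json()].
#' @return An `annotation_record`.
#' @export
parse_annotation_record <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  x$annotations <- lapply(x$annotations, function(a) {
    a$tags <- lapply(a$tags, function(t) list(name = t$name, uri = t$uri))
    a[c("exact", "prefix", "postfix", "section", "entity_type", "tags")]
  })
  structure(
    list(
      collection = x$collection,
      article_id = x$article_id,
      provider = x$provider,
      annotations = x$annotations
    ),
    class = "annotation_record"
  )
}

#' Parse ENA-style study XML
#'
#' Collects accessions from `ENA-SAMPLE`, `ENA-EXPERIMENT`, and `ENA-RUN`
#' tags; missing tags yield empty lists.
#'
#' @param xml Path to an XML file or an XML string.
#' @return A list with `study_id`, `sample_accessions`,
#'   `experiment_accessions`, `run_accessions`.
#' @export
parse_study_xml <- function(xml) {
  node <- tryCatch(
    xml2::read_xml(xml),
    error = function(e) {
      stop("malformed study XML: ", conditionMessage(e), call. = FALSE)
    }
  )
  grab <- function(tag) {
    xml2::xml_text(xml2::xml_find_all(node, paste0(".//", tag)))
  }
  list(
    study_id = xml2::xml_attr(node, "accession"),
    sample_accessions = grab("ENA-SAMPLE"),
    experiment_accessions = grab("ENA-EXPERIMENT"),
    run_accessions = grab("ENA-RUN")
  )
}

canonicalize_value <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Pool study metadata onto MIxS terms
#'
#' Values from submitted fields and from annotation entities are
#' canonicalized (trim, collapse internal whitespace, case-fold) and pooled
#' per MIxS term. Unmapped fields and entity types are excluded and counted
#' in the `"coverage"` attribute.
#'
#' @param submitted A tibble with columns `field`, `value` for one study.
#' @param annotations A tibble with columns `entity_type`, `exact` for the
#'   study's publications.
#' @param entity_mapping Entity type to MIxS term table
#'   ([default_mixs_mapping()]).
#' @param field_mapping Submitted field to MIxS term table
#'   ([default_field_mapping()]).
#' @return A tibble with columns `mixs_term`, `submitted` (list of value
#'   sets), `annotated` (list of value sets), covering every term in either
#'   mapping.
#' @export
pool_metadata <- function(submitted, annotations,
                          entity_mapping = default_mixs_mapping(),
                          field_mapping = default_field_mapping()) {
  unmapped_fields <- setdiff(unique(submitted$field), field_mapping$field)
  unmapped_entities <- submitted_terms <- NULL
  sub <- submitted |>
    inner_join(field_mapping, by = "field") |>
    filter(.data$mixs_term != "unmapped") |>
    mutate(value = canonicalize_value(.data$value)) |>
    group_by(.data$mixs_term) |>
    summarise(submitted = list(unique(.data$value)), .groups = "drop")
  mapped_ann <- annotations |>
    inner_join(entity_mapping, by = "entity_type") |>
    filter(.data$mixs_term != "unmapped")
  unmapped_entities <- setdiff(
    unique(annotations$entity_type),
    entity_mapping$entity_type[entity_mapping$mixs_term != "unmapped"]
  )
  ann <- mapped_ann |>
    mutate(value = canonicalize_value(.data$exact)) |>
    group_by(.data$mixs_term) |>
    summarise(annotated = list(unique(.data$value)), .groups = "drop")
  terms <- union(
    setdiff(unique(field_mapping$mixs_term), "unmapped"),
    setdiff(unique(entity_mapping$mixs_term), "unmapped")
  )
  out <- tibble::tibble(mixs_term = sort(terms)) |>
    left_join(sub, by = "mixs_term") |>
    left_join(ann, by = "mixs_term") |>
    mutate(
      submitted = purrr::map(.data$submitted, function(v) {
        if (is.null(v)) character(0) else v
      }),
      annotated = purrr::map(.data$annotated, function(v) {
        if (is.null(v)) character(0) else v
      })
    )
  structure(out, coverage = list(
    unmapped_fields = unmapped_fields,
    unmapped_entities = unmapped_entities
  ))
}

#' Compare pooled metadata per MIxS term
#'
#' Per term: both pools non-empty and intersecting is `identical` (any one
#' shared value suffices); both non-empty and disjoint is `nonidentical`;
#' exactly one non-empty is `unique_submitted` / `unique_annotation`; both
#' empty is `absent`. Exactly one status per term.
#'
#' @param pools A tibble from [pool_metadata()].
#' @return A tibble with columns `mixs_term`, `status`.
#' @export
compare_study <- function(pools) {
  status <- purrr::map2_chr(pools$submitted, pools$annotated, function(s, a) {
    has_s <- length(s) > 0
    has_a <- length(a) > 0
    if (has_s && has_a) {
      if (length(intersect(s, a)) > 0) "identical" else "nonidentical"
    } else if (has_s) {
      "unique_submitted"
    } else if (has_a) {
      "unique_annotation"
    } else {
      "absent"
    }
  })
  tibble::tibble(mixs_term = pools$mixs_term, status = status)
}

#' Compare submitted vs publication-derived metadata across studies
#'
#' @param studies A studies tibble (with `study_id`, `publication_ids`).
#' @param submitted_metadata A tibble `study_id`, `field`, `value`.
#' @param annotations An annotation tibble with `doc_id`, `entity_type`,
#'   `exact` (curated or predicted).
#' @param entity_mapping,field_mapping MIxS mapping tables.
#' @return A tibble of comparison cells: `study_id`, `mixs_term`, `status`.
#' @export
compare_studies <- function(studies, submitted_metadata, annotations,
                            entity_mapping = default_mixs_mapping(),
                            field_mapping = default_field_mapping()) {
  purrr::map(seq_len(nrow(studies)), function(i) {
    sid <- studies$study_id[i]
    docs <- studies$publication_ids[[i]]
    pools <- pool_metadata(
      submitted_metadata |> filter(.data$study_id == sid),
      annotations |> filter(.data$doc_id %in% docs),
      entity_mapping, field_mapping
    )
    compare_study(pools) |> mutate(study_id = sid, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Summarise comparison cells per MIxS term
#'
#' Counts studies by status per term, excluding `absent`; terms are ranked
#' by total. The field filter applies to submitted fields: a term backed
#' only by submitted fields must be observed in more than
#' `min_studies_per_field` studies, while entity-mapped terms always pass.
#'
#' @param cells Comparison cells from [compare_studies()].
#' @param entity_mapping Entity mapping used to identify entity-backed
#'   terms.
#' @param min_studies_per_field Submitted-field support threshold.
#' @return A tibble `mixs_term`, `status`, `n_studies`, ordered by per-term
#'   totals, of class `mixs_summary`.
#' @export
summarize_comparison <- function(cells,
                                 entity_mapping = default_mixs_mapping(),
                                 min_studies_per_field = 50) {
  non_absent <- cells |> filter(.data$status != "absent")
  entity_terms <- setdiff(unique(entity_mapping$mixs_term), "unmapped")
  submitted_support <- non_absent |>
    filter(.data$status %in% c("identical", "nonidentical",
                               "unique_submitted")) |>
    distinct(.data$study_id, .data$mixs_term) |>
    count(.data$mixs_term, name = "n_submitted")
  keep <- union(
    entity_terms,
    submitted_support$mixs_term[
      submitted_support$n_submitted > min_studies_per_field
    ]
  )
  out <- non_absent |>
    filter(.data$mixs_term %in% keep) |>
    count(.data$mixs_term, .data$status, name = "n_studies")
  totals <- out |>
    group_by(.data$mixs_term) |>
    summarise(total = sum(.data$n_studies), .groups = "drop")
  out <- out |>
    left_join(totals, by = "mixs_term") |>
    arrange(desc(.data$total), .data$mixs_term, .data$status) |>
    select(-"total")
  class(out) <- c("mixs_summary", class(out))
  out
}

#' Plot a stacked per-term comparison summary
#'
#' @param object A `mixs_summary`.
#' @param ... Ignored.
#' @return A ggplot object: one stacked bar per MIxS term showing study
#'   counts by comparison status.
#' @export
autoplot.mixs_summary <- function(object, ...) {
  lv <- object |>
    group_by(.data$mixs_term) |>
    summarise(total = sum(.data$n_studies), .groups = "drop") |>
    arrange(.data$total)
  dat <- object |>
    mutate(mixs_term = factor(.data$mixs_term, levels = lv$mixs_term))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mixs_term,
                                    y = .data$n_studies,
                                    fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Studies",
                  title = "Submitted vs publication-derived metadata") +
    ggplot2::theme_minimal()
}
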