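# The 16-type metagenomics entity schema covering biome and experimental
# metadata mined from publications.

#' The metagenomics entity schema
#'
#' Sixteen entity types covering biome metadata (where a sample came from)
#' and experimental metadata (how it was processed and sequenced). Each
#' type gets its own BIO dataset and its own sequence labeler because
#' mentions of different types may nest or overlap on the same tokens.
#'
#' @return A tibble with columns `entity_type` and `definition` (16 rows).
#' @export
entity_schema <- function() {
  tibble::tribble(
    ~entity_type,      ~definition,
    "ecoregion",       "Microbiome natural environment",
    "host",            "Microbiome living organism or host",
    "engineered",      "Microbiome humanmade environment",
    "date",            "Microbiome sample collection date",
    "place",           "The place of microbiome environment or host",
    "site",            "The site of microbiome sample within place",
    "body-site",       "The organ or tissue of microbiome sample",
    "sample-material", "The material of the microbiome sample (e.g., water, mucus, soil)",
    "state",           "The state of the microbiome environment or host (e.g., disease)",
    "treatment",       "Any treatment performed on the host or the environment sampled",
    "kit",             "DNA extraction kit",
    "primer",          "PCR primers",
    "gene",            "Microbiome target genes (e.g., rRNA subunit and amplified regions)",
    "LS",              "Library source or library strategy (e.g., amplicon, whole genome)",
    "LCM",             "Library construction method or layout (e.g., paired end, single end)",
    "sequencing",      "Sequencing platform"
  )
}

#' Entity type names
#'
#' @return Character vector of the 16 entity type names, in schema order.
#' @export
entity_types <- function() {
  entity_schema()$entity_type
}

check_entity_type <- function(types) {
  bad <- setdiff(unique(types), entity_types())
  if (length(bad) > 0) {
    stop("unknown entity type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(types)
}
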