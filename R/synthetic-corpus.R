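# Synthetic corpora with known ground truth: sectioned documents whose
# non-methods sections carry biome-class vocabulary and whose methods
# sections carry templated entity mentions; plus study records, biome
# lineages, and submitted metadata with controllable missingness and
# format inconsistency. Every downstream stage of the pipeline is testable
# against the generator's truth.

biome_classes <- function() c("Engineered", "Environmental", "Host-associated")

default_class_vocabularies <- function() {
  list(
    "Environmental" = c(
      "ocean", "marine", "seawater", "sediment", "river", "lake", "forest",
      "soil", "tundra", "desert", "glacier", "estuary", "wetland", "plankton",
      "coastal", "freshwater", "benthic", "pelagic", "watershed", "alpine",
      "grassland", "peatland", "lagoon", "reef", "groundwater", "permafrost",
      "salinity", "upwelling", "biome", "catchment"
    ),
    "Engineered" = c(
      "bioreactor", "wastewater", "sludge", "digester", "fermentation",
      "effluent", "compost", "biofilter", "brewery", "dairy", "silage",
      "biogas", "anaerobic", "reactor", "industrial", "pipeline", "membrane",
      "aeration", "tofu", "factory", "fermenter", "koji", "vinegar",
      "bioleaching", "electrode", "landfill", "tannery", "distillery",
      "clarifier", "influent"
    ),
    "Host-associated" = c(
      "gut", "fecal", "intestinal", "oral", "skin", "rumen", "cecal",
      "mucosa", "host", "mouse", "human", "chicken", "bovine", "porcine",
      "infant", "patient", "colon", "nasal", "vaginal", "tissue",
      "microbiota", "immune", "diet", "probiotic", "lesion", "biopsy",
      "stool", "saliva-associated", "gingival", "epithelium"
    )
  )
}

# Per-section cue words so the five canonical section types are learnable
# by the section classifier (and methods text is recoverable when a
# document's headings are missing).
default_section_cues <- function() {
  list(
    "abstract" = c("overview", "summarize", "briefly", "highlights",
                   "report", "presented"),
    "introduction" = c("background", "previous", "motivation", "hypothesis",
                       "known", "remains", "challenge", "aim"),
    "methods" = c("protocol", "procedure", "performed", "extracted",
                  "incubated", "centrifuged", "prepared", "processed"),
    "results" = c("observed", "increased", "decreased", "measured",
                  "figure", "significant", "detected", "higher"),
    "discussion" = c("suggests", "interpretation", "limitations",
                     "implications", "consistent", "future", "contrast",
                     "supports")
  )
}

default_shared_vocabulary <- function() {
  c(
    "samples", "were", "collected", "the", "dna", "extracted", "sequencing",
    "analysis", "microbial", "community", "diversity", "study", "data",
    "using", "performed", "reads", "amplified", "abundance", "taxa",
    "composition", "observed", "significant", "results", "between", "among",
    "total", "obtained", "based", "protocol", "library", "preparation",
    "relative", "profiles", "richness", "clusters", "replicates",
    "normalized", "assembly", "annotation", "comparison"
  )
}

#' Default entity lexicons for the synthetic generator
#'
#' One surface-form list per schema type, including multi-word forms,
#' primer strings with characters outside the fixture vocabulary, and
#' site forms whose first word is a place form (nested span pairs).
#'
#' @return Named list (one element per entity type) of character vectors.
#' @export
default_entity_lexicons <- function() {
  places <- c("Nevada", "Namibia", "Yunnan", "Atacama", "Queensland",
              "Hokkaido", "Patagonia", "Svalbard")
  list(
    "ecoregion" = c("Namib Desert", "boreal forest belt", "coral reef flat",
                    "alpine tundra zone", "mangrove swamp", "peat bog",
                    "kelp forest strip", "salt flat basin"),
    "host" = c("Mus musculus", "Homo sapiens", "Gallus gallus", "Bos taurus",
               "Apis mellifera", "Danio rerio", "Sus scrofa", "Ovis aries"),
    "engineered" = c("anaerobic digester tank", "wastewater treatment plant",
                     "microbial fuel cell", "tofu production line",
                     "biogas reactor vessel", "drinking water main",
                     "compost windrow", "membrane bioreactor unit"),
    "date" = c("June 2015", "March 2018", "15 July 2019", "2014",
               "October 2020", "January 2016", "2017", "August 2013"),
    "place" = places,
    "site" = paste(places, c("hot springs", "gravel plains",
                             "rice paddies", "salt lakes",
                             "sugarcane fields", "onsen pools",
                             "glacial lakes", "fjord sediments")),
    "body-site" = c("posterior vaginal fornix", "oral cavity", "cecal mucosa",
                    "skin surface", "distal colon", "nasal cavity",
                    "rumen wall", "gill tissue"),
    "sample-material" = c("surface water", "rhizosphere soil",
                          "activated sludge flocs", "fecal pellets",
                          "whole saliva", "leaf litter", "marine mud",
                          "mucus layer"),
    "state" = c("100-year drought", "mesotrophic condition", "gingivitis",
                "oropharyngeal mucositis", "denitrification regime",
                "eutrophic condition", "dental caries", "poor oral hygiene"),
    "treatment" = c("benzylpenicillin", "probiotic supplementation",
                    "nitrogen fertilizer", "vancomycin", "metronidazole",
                    "cefotaxime", "soil fumigation", "gentamicin"),
    "kit" = c("RNA PowerSoil total RNA isolation kit",
              "DNeasy PowerSoil kit", "FastDNA SPIN kit",
              "QIAamp DNA stool mini kit", "MoBio PowerWater kit",
              "AllPrep DNA RNA mini kit",
              "PureLink microbiome purification kit",
              "ZymoBIOMICS DNA miniprep kit"),
    "primer" = c("5′-ACACTCTTTCCCTACACGACGCTC-3′",
                 "5′-GTGCCAGCMGCCGCGGTAA-3′",
                 "5′-GGACTACHVGGGTWTCTAAT-3′",
                 "5′-CCTACGGGNGGCWGCAG-3′",
                 "5′-GACTACNVGGGTATCTAATCC-3′",
                 "5′-AGRGTTYGATYMTGGCTCAG-3′",
                 "5′-TACGGYTACCTTGTTACGACTT-3′",
                 "5′-GTGYCAGCMGCCGCGGTAA-3′"),
    "gene" = c("16S ribosomal RNA", "V3–V4 region", "18S rRNA gene",
               "ITS2 spacer", "nifH marker", "amoA marker", "mcrA marker",
               "cpn60 marker"),
    "LS" = c("amplicon", "whole genome shotgun", "metatranscriptome",
             "16S amplicon", "metagenome", "RNA-Seq", "WGS", "shotgun run"),
    "LCM" = c("paired end", "single end", "2x250 bp paired end", "mate pair",
              "2x150 bp", "fragment library prep", "nextera paired end",
              "long read"),
    "sequencing" = c("Illumina MiSeq", "Illumina HiSeq 2500",
                     "Ion Torrent PGM", "PacBio Sequel",
                     "Oxford Nanopore MinION", "Illumina NovaSeq 6000",
                     "Roche 454 GS FLX", "BGISEQ-500")
  )
}

# Methods-section cue templates: c(prefix, suffix) around the planted form.
entity_templates <- function() {
  list(
    "ecoregion" = c("Samples were collected across the ", " during the survey."),
    "host" = c("Specimens were obtained from ", " individuals."),
    "engineered" = c("Influent material was sourced from a ", " on site."),
    "date" = c("Sampling was conducted in ", " at each station."),
    "place" = c("Field stations were situated in ", " for this campaign."),
    "site" = c("Cores were retrieved from the ", " at low tide."),
    "body-site" = c("Swabs were taken from the ", " of each subject."),
    "sample-material" = c("Each specimen consisted of ", " kept on ice."),
    "state" = c("Conditions were characterized by ", " throughout."),
    "treatment" = c("Subjects received ", " before collection."),
    "kit" = c("DNA was extracted using the ", " following the manual."),
    "primer" = c("Amplification was performed with primer ", " in triplicate."),
    "gene" = c("Libraries targeted the ", " for profiling."),
    "LS" = c("Libraries were prepared with the ", " strategy."),
    "LCM" = c("Sequencing was run in ", " mode."),
    "sequencing" = c("Reads were generated on the ", " platform.")
  )
}

default_lineages <- function() {
  list(
    "Engineered" = list(
      c("Engineered", "Wastewater", "Activated sludge"),
      c("Engineered", "Food production", "Fermented food", "Soybean product"),
      c("Engineered", "Bioreactor", "Anaerobic digester")
    ),
    "Environmental" = list(
      c("Environmental", "Aquatic", "Marine", "Coastal", "Sediment"),
      c("Environmental", "Terrestrial", "Soil", "Desert"),
      c("Environmental", "Aquatic", "Freshwater", "Lake")
    ),
    "Host-associated" = list(
      c("Host-associated", "Mammals", "Digestive system", "Large intestine",
        "Fecal"),
      c("Host-associated", "Human", "Oral cavity"),
      c("Host-associated", "Birds", "Digestive system")
    )
  )
}

#' Generator configuration
#'
#' Defines the study conditions the synthetic corpus emulates. All
#' randomness downstream of [generate_bundle()] flows from a single stream
#' seeded once with `seed`.
#'
#' @param seed Integer seed for the bundle's pseudo-random stream.
#' @param n_docs_per_class Named integer vector: documents per biome class.
#' @param mixture Fraction of class-specific tokens per non-methods
#'   sentence, in `[0, 1]`; higher is more separable.
#' @param plant_rate Expected entity mentions per methods sentence, in
#'   `[0, 1]` (each methods sentence carries at most one templated mention).
#' @param metadata_missingness Probability a submitted metadata field is
#'   dropped for a study, in `[0, 1]`.
#' @param metadata_inconsistency Probability a submitted field keeps a
#'   format-variant value (e.g. "June 2015" vs "2015"), in `[0, 1]`.
#' @param n_methods_sentences Sentences per methods section.
#' @param class_vocabularies Named list of per-class word vectors (optionally
#'   with numeric weights as names-on-values via a named numeric vector).
#' @param shared_vocabulary Word vector shared by all classes.
#' @param entity_lexicons Named list of surface-form vectors, one per entity
#'   type in the 16-type schema; every type must be non-empty.
#' @param corpus_label Short label prefixed to generated doc ids, so bundles
#'   with different labels are disjoint by construction.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 9,
                             n_docs_per_class = c(
                               "Engineered" = 20, "Environmental" = 20,
                               "Host-associated" = 20
                             ),
                             mixture = 0.8,
                             plant_rate = 0.9,
                             metadata_missingness = 0.2,
                             metadata_inconsistency = 0.15,
                             n_methods_sentences = 8,
                             class_vocabularies = default_class_vocabularies(),
                             shared_vocabulary = default_shared_vocabulary(),
                             entity_lexicons = default_entity_lexicons(),
                             corpus_label = "A") {
  fracs <- c(mixture = mixture, plant_rate = plant_rate,
             metadata_missingness = metadata_missingness,
             metadata_inconsistency = metadata_inconsistency)
  if (any(fracs < 0 | fracs > 1)) {
    stop("mixture, plant_rate, missingness and inconsistency must lie in [0, 1]",
         call. = FALSE)
  }
  missing_types <- setdiff(entity_types(), names(entity_lexicons))
  empty_types <- names(entity_lexicons)[
    vapply(entity_lexicons, length, 1L) == 0
  ]
  if (length(missing_types) || length(empty_types)) {
    stop("every entity type needs a non-empty lexicon; offending: ",
         paste(unique(c(missing_types, empty_types)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(n_docs_per_class)) ||
      !all(names(n_docs_per_class) %in% biome_classes())) {
    stop("n_docs_per_class must be named with biome classes", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_docs_per_class = n_docs_per_class,
      mixture = mixture,
      plant_rate = plant_rate,
      metadata_missingness = metadata_missingness,
      metadata_inconsistency = metadata_inconsistency,
      n_methods_sentences = as.integer(n_methods_sentences),
      class_vocabularies = class_vocabularies,
      shared_vocabulary = shared_vocabulary,
      entity_lexicons = entity_lexicons,
      corpus_label = corpus_label
    ),
    class = "generator_config"
  )
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sample_words <- function(words, n) {
  prob <- NULL
  if (is.numeric(words)) {
    prob <- unname(words)
    words <- names(words)
  }
  sample(words, n, replace = TRUE, prob = prob)
}

vocab_sentence <- function(class_vocab, shared_vocab, mixture, cues = NULL) {
  n <- sample(8:14, 1)
  from_class <- stats::runif(n) < mixture
  words <- character(n)
  if (any(from_class)) words[from_class] <- sample_words(class_vocab, sum(from_class))
  if (any(!from_class)) words[!from_class] <- sample_words(shared_vocab, sum(!from_class))
  if (!is.null(cues)) {
    slots <- sample.int(n, min(2L, n))
    words[slots] <- sample_words(cues, length(slots))
  }
  words[1] <- paste0(toupper(substr(words[1], 1, 1)), substring(words[1], 2))
  paste0(paste(words, collapse = " "), ".")
}

clip_context <- function(text, width = 30) {
  if (nchar(text) <= width) return(text)
  substring(text, nchar(text) - width + 1)
}

# Build one methods sentence with a planted entity; returns sentence text
# plus annotation rows (possibly two for a nested site/place pair).
plant_sentence <- function(type, form, lexicons) {
  tpl <- entity_templates()[[type]]
  pre <- tpl[1]
  post <- tpl[2]
  text <- paste0(pre, form, post)
  start <- nchar(pre)
  end <- start + nchar(form)
  ann <- tibble::tibble(
    entity_type = type,
    char_start = start, char_end = end,
    exact = form,
    prefix = clip_context(substr(text, 1, start)),
    suffix = substr(text, end + 1, end + 30)
  )
  if (type == "site") {
    inner <- lexicons[["place"]][
      vapply(lexicons[["place"]], function(p) startsWith(form, paste0(p, " ")),
             TRUE)
    ]
    if (length(inner) == 1) {
      in_end <- start + nchar(inner)
      ann <- dplyr::bind_rows(ann, tibble::tibble(
        entity_type = "place",
        char_start = start, char_end = in_end,
        exact = inner,
        prefix = clip_context(substr(text, 1, start)),
        suffix = substr(text, in_end + 1, in_end + 30)
      ))
    }
  }
  list(text = text, annotations = ann)
}

assemble_section <- function(doc_id, section_idx, heading, canonical_type,
                             sentence_texts) {
  n <- length(sentence_texts)
  lens <- nchar(sentence_texts)
  ends <- cumsum(lens + 1L) - 1L
  starts <- ends - lens
  tibble::tibble(
    heading = heading,
    canonical_type = canonical_type,
    sentences = list(tibble::tibble(
      sent_id = sentence_ids(doc_id, section_idx, n),
      text = sentence_texts,
      char_start = as.integer(starts),
      char_end = as.integer(ends)
    ))
  )
}

year_of <- function(x) {
  y <- regmatches(x, regexpr("[0-9]{4}", x))
  if (length(y) == 0) NA_character_ else y
}

# Format variant used to emulate inconsistent author-submitted metadata.
variant_value <- function(value, entity_type) {
  if (entity_type == "date") {
    y <- year_of(value)
    if (!is.na(y) && y != value) return(y)
    return(paste("ca.", value))
  }
  first <- strsplit(value, " ", fixed = TRUE)[[1]][1]
  if (identical(first, value)) paste(value, "v2") else first
}

#' Default entity type to MIxS term mapping
#'
#' Editable seed mapping from the 16 entity types to MIxS checklist terms.
#'
#' @return A tibble with columns `entity_type` and `mixs_term` (a type may
#'   map to `"unmapped"`).
#' @export
default_mixs_mapping <- function() {
  tibble::tribble(
    ~entity_type,      ~mixs_term,
    "ecoregion",       "env_broad_scale",
    "host",            "specific_host",
    "engineered",      "env_broad_scale",
    "date",            "collection_date",
    "place",           "geo_loc_name",
    "site",            "env_local_scale",
    "body-site",       "env_local_scale",
    "sample-material", "env_medium",
    "state",           "health_disease_stat",
    "treatment",       "env_package",
    "kit",             "nucl_acid_ext",
    "primer",          "pcr_primers",
    "gene",            "target_gene",
    "LS",              "lib_strategy",
    "LCM",             "lib_layout",
    "sequencing",      "seq_meth"
  )
}

#' Default submitted-field to MIxS term mapping
#'
#' ENA-style submitted metadata field names and the MIxS terms they map to.
#'
#' @return A tibble with columns `field` and `mixs_term`.
#' @export
default_field_mapping <- function() {
  tibble::tribble(
    ~field,                         ~mixs_term,
    "collection date",              "collection_date",
    "geographic location",          "geo_loc_name",
    "host scientific name",         "specific_host",
    "pcr primers",                  "pcr_primers",
    "target gene",                  "target_gene",
    "nucleic acid extraction",      "nucl_acid_ext",
    "library layout",               "lib_layout",
    "library strategy",             "lib_strategy",
    "instrument model",             "seq_meth",
    "environment biome",            "env_broad_scale",
    "environment material",         "env_medium",
    "environment feature",          "env_local_scale",
    "environmental package",        "env_package",
    "health state",                 "health_disease_stat"
  )
}

#' Generate a synthetic gold bundle
#'
#' Produces a sectioned document corpus, biome labels, curated span
#' annotations (anchored, with exact/prefix/suffix context), study records
#' cross-referencing the documents, and submitted study metadata that agrees
#' with the planted annotations except at the configured missingness and
#' inconsistency rates. Deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @return An object of class `mm_bundle`: a list with elements `config`,
#'   `documents` (corpus tibble), `biome_labels`, `annotations`, `studies`,
#'   and `submitted_metadata`.
#' @export
generate_bundle <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, generate_bundle_impl(config))
}

generate_bundle_impl <- function(config) {
  lexicons <- config$entity_lexicons
  types <- entity_types()
  lineages <- default_lineages()
  class_abbrev <- c("Engineered" = "eng", "Environmental" = "env",
                    "Host-associated" = "host")

  docs <- list()
  labels <- list()
  annotations <- list()

  for (class in names(config$n_docs_per_class)) {
    n_docs <- config$n_docs_per_class[[class]]
    cvocab <- config$class_vocabularies[[class]]
    for (d in seq_len(n_docs)) {
      doc_id <- sprintf("%s-%s-%03d", config$corpus_label,
                        class_abbrev[[class]], d)
      source_id <- sprintf("PMC%07d", sample.int(9999999, 1))
      title <- vocab_sentence(cvocab, config$shared_vocabulary, config$mixture)
      plan <- list(
        c("Abstract", "abstract", 3),
        c("Introduction", "introduction", 4),
        c("Materials and Methods", "methods", config$n_methods_sentences),
        c("Results", "results", 4),
        c("Discussion", "discussion", 3)
      )
      sections <- list()
      used_forms <- character(0)
      for (si in seq_along(plan)) {
        heading <- plan[[si]][1]
        ctype <- plan[[si]][2]
        n_sent <- as.integer(plan[[si]][3])
        texts <- character(n_sent)
        for (k in seq_len(n_sent)) {
          plant <- ctype == "methods" && stats::runif(1) < config$plant_rate
          if (plant) {
            type <- sample(types, 1)
            avail <- setdiff(lexicons[[type]], used_forms)
            if (length(avail) == 0) plant <- FALSE else {
              form <- if (length(avail) == 1) avail else sample(avail, 1)
              used_forms <- c(used_forms, form)
              planted <- plant_sentence(type, form, lexicons)
              texts[k] <- planted$text
              sid <- sprintf("%s:s%d:%d", doc_id, si, k)
              annotations[[length(annotations) + 1]] <-
                dplyr::mutate(planted$annotations,
                              doc_id = doc_id, sent_id = sid,
                              provenance = "curated")
            }
          }
          if (!plant) {
            vocab <- if (ctype == "methods") config$shared_vocabulary else cvocab
            texts[k] <- vocab_sentence(
              vocab, config$shared_vocabulary,
              if (ctype == "methods") 0 else config$mixture,
              cues = default_section_cues()[[ctype]]
            )
          }
        }
        sections[[si]] <- assemble_section(doc_id, si, heading, ctype, texts)
      }
      docs[[length(docs) + 1]] <-
        new_document(doc_id, source_id, title, dplyr::bind_rows(sections))
      labels[[length(labels) + 1]] <- tibble::tibble(
        doc_id = doc_id, class = class
      )
    }
  }

  documents <- dplyr::bind_rows(docs)
  biome_labels <- dplyr::bind_rows(labels)
  annotations <- if (length(annotations)) {
    dplyr::bind_rows(annotations) |>
      select("doc_id", "sent_id", "entity_type", "char_start", "char_end",
             "exact", "prefix", "suffix", "provenance")
  } else {
    tibble::tibble(
      doc_id = character(), sent_id = character(), entity_type = character(),
      char_start = integer(), char_end = integer(), exact = character(),
      prefix = character(), suffix = character(), provenance = character()
    )
  }

  # Studies: partition each class's documents into studies of 1-2 documents.
  studies <- list()
  acc_counter <- 0L
  for (class in names(config$n_docs_per_class)) {
    ids <- biome_labels$doc_id[biome_labels$class == class]
    i <- 1L
    while (i <= length(ids)) {
      take <- min(sample(1:2, 1), length(ids) - i + 1L)
      study_docs <- ids[i:(i + take - 1L)]
      i <- i + take
      acc_counter <- acc_counter + 1L
      lineage <- lineages[[class]][[sample.int(length(lineages[[class]]), 1)]]
      n_s <- sample(1:3, 1)
      studies[[length(studies) + 1]] <- tibble::tibble(
        study_id = sprintf("MGYS%05d", acc_counter),
        biome_class = class,
        biome_lineage = list(lineage),
        publication_ids = list(study_docs),
        sample_accessions = list(sprintf("SRS%06d", acc_counter * 10L + seq_len(n_s))),
        experiment_accessions = list(sprintf("SRX%06d", acc_counter * 10L + seq_len(n_s))),
        run_accessions = list(sprintf("SRR%06d", acc_counter * 10L + seq_len(n_s)))
      )
    }
  }
  studies <- dplyr::bind_rows(studies)

  # Submitted metadata: per study, pool annotation values by MIxS term and
  # degrade by missingness / format inconsistency.
  mapping <- default_mixs_mapping()
  fields <- default_field_mapping()
  submitted <- list()
  for (s in seq_len(nrow(studies))) {
    study_docs <- studies$publication_ids[[s]]
    anns <- annotations |>
      filter(.data$doc_id %in% study_docs) |>
      inner_join(mapping, by = "entity_type") |>
      filter(.data$mixs_term != "unmapped")
    if (nrow(anns) == 0) next
    by_term <- anns |>
      group_by(.data$mixs_term) |>
      summarise(
        values = list(unique(.data$exact)),
        entity_type = dplyr::first(.data$entity_type),
        .groups = "drop"
      )
    for (t in seq_len(nrow(by_term))) {
      if (stats::runif(1) < config$metadata_missingness) next
      term <- by_term$mixs_term[t]
      field <- fields$field[match(term, fields$mixs_term)]
      if (is.na(field)) next
      vals <- by_term$values[[t]]
      if (stats::runif(1) < config$metadata_inconsistency) {
        vals <- vapply(vals, variant_value, "",
                       entity_type = by_term$entity_type[t])
      }
      submitted[[length(submitted) + 1]] <- tibble::tibble(
        study_id = studies$study_id[s], field = field, value = unname(vals)
      )
    }
  }
  submitted <- if (length(submitted)) dplyr::bind_rows(submitted) else
    tibble::tibble(study_id = character(), field = character(),
                   value = character())

  structure(
    list(
      config = config,
      documents = documents,
      biome_labels = biome_labels,
      annotations = annotations,
      studies = studies,
      submitted_metadata = submitted
    ),
    class = "mm_bundle"
  )
}

#' @export
print.mm_bundle <- function(x, ...) {
  cat("<mm_bundle>", nrow(x$documents), "documents,",
      nrow(x$annotations), "annotations,",
      nrow(x$studies), "studies\n")
  invisible(x)
}

#' Summarise a bundle's ground truth
#'
#' @param bundle An `mm_bundle`.
#' @return A tibble with columns `quantity`, `key`, `n`: document counts per
#'   biome class, annotation counts per entity type, the number of studies,
#'   and submitted metadata cells per MIxS term.
#' @export
truth_report <- function(bundle) {
  stopifnot(inherits(bundle, "mm_bundle"))
  docs <- bundle$biome_labels |>
    count(.data$class, name = "n") |>
    transmute(quantity = "documents", key = .data$class, n = .data$n)
  anns <- bundle$annotations |>
    count(.data$entity_type, name = "n") |>
    transmute(quantity = "annotations", key = .data$entity_type, n = .data$n)
  studies <- tibble::tibble(
    quantity = "studies", key = "total", n = nrow(bundle$studies)
  )
  cells <- bundle$submitted_metadata |>
    inner_join(default_field_mapping(), by = "field") |>
    distinct(.data$study_id, .data$mixs_term) |>
    count(.data$mixs_term, name = "n") |>
    transmute(quantity = "metadata_cells", key = .data$mixs_term, n = .data$n)
  dplyr::bind_rows(docs, anns, studies, cells)
}

#' Write a bundle's study records as ENA-style study XML files
#'
#' One XML file per study with `ENA-SAMPLE`, `ENA-EXPERIMENT`, and
#' `ENA-RUN` accession tags.
#'
#' @param studies The `studies` tibble of an `mm_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_xml <- function(studies, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(studies))) {
    root <- xml2::xml_new_root("STUDY")
    xml2::xml_set_attr(root, "accession", studies$study_id[i])
    links <- xml2::xml_add_child(root, "STUDY_LINKS")
    for (acc in studies$sample_accessions[[i]]) {
      xml2::xml_add_child(links, "ENA-SAMPLE", acc)
    }
    for (acc in studies$experiment_accessions[[i]]) {
      xml2::xml_add_child(links, "ENA-EXPERIMENT", acc)
    }
    for (acc in studies$run_accessions[[i]]) {
      xml2::xml_add_child(links, "ENA-RUN", acc)
    }
    xml2::write_xml(root, file.path(dir, paste0(studies$study_id[i], ".xml")))
  }
  invisible(dir)
}

#' Write a bundle to a directory of plain-text artifacts
#'
#' Writes `corpus.jsonl`, `annotations.jsonl`, `studies.jsonl`,
#' `submitted_metadata.tsv`, and a `studies_xml/` directory.
#'
#' @param bundle An `mm_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus_jsonl(bundle$documents, file.path(dir, "corpus.jsonl"))
  write_annotations_jsonl(bundle$annotations,
                          file.path(dir, "annotations.jsonl"))
  write_studies_jsonl(bundle$studies, bundle$biome_labels,
                      file.path(dir, "studies.jsonl"))
  utils::write.table(
    bundle$submitted_metadata, file.path(dir, "submitted_metadata.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  write_study_xml(bundle$studies, file.path(dir, "studies_xml"))
  invisible(dir)
}

#' Write annotations as JSONL
#'
#' @param annotations Annotation tibble (as in an `mm_bundle`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_jsonl <- function(annotations, path) {
  lines <- purrr::map_chr(seq_len(nrow(annotations)), function(i) {
    jsonlite::toJSON(as.list(annotations[i, ]), auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read annotations from JSONL
#'
#' @param path Input file path.
#' @return An annotation tibble.
#' @export
read_annotations_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- purrr::imap(lines, function(line, i) {
    x <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = TRUE),
      error = function(e) {
        stop("malformed JSONL at line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    tibble::as_tibble(x)
  })
  dplyr::bind_rows(rows)
}

write_studies_jsonl <- function(studies, biome_labels, path) {
  lines <- purrr::map_chr(seq_len(nrow(studies)), function(i) {
    jsonlite::toJSON(
      list(
        study_id = studies$study_id[i],
        biome_lineage = studies$biome_lineage[[i]],
        publication_ids = studies$publication_ids[[i]]
      ),
      auto_unbox = TRUE, digits = NA
    )
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read study records from JSONL
#'
#' One object per line with keys `study_id`, `biome_lineage` (ordered list,
#' levels 1..5), and `publication_ids`.
#'
#' @param path Input file path.
#' @return A tibble with columns `study_id`, `biome_lineage` (list),
#'   `publication_ids` (list).
#' @export
read_studies_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- purrr::imap(lines, function(line, i) {
    x <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = TRUE),
      error = function(e) {
        stop("malformed JSONL at line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    tibble::tibble(
      study_id = x$study_id,
      biome_lineage = list(as.character(x$biome_lineage)),
      publication_ids = list(as.character(x$publication_ids))
    )
  })
  dplyr::bind_rows(rows)
}
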