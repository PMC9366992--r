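one_kit_doc <- function() {
  text <- "DNA was extracted using the FastDNA SPIN kit following the manual."
  new_document("d1", "PMC0000001", "Title", tibble::tibble(
    heading = "Methods", canonical_type = "methods",
    sentences = list(tibble::tibble(
      sent_id = "d1:s1:1", text = text,
      char_start = 0L, char_end = nchar(text)
    ))
  ))
}

kit_span <- function() {
  tibble::tibble(
    doc_id = "d1", sent_id = "d1:s1:1", entity_type = "kit",
    char_start = 28L, char_end = 44L, exact = "FastDNA SPIN kit"
  )
}

test_that("annotation records carry span context, entity type, and mapper tags", {
  rec <- emit_annotations(one_kit_doc(), kit_span())
  expect_s3_class(rec, "annotation_record")
  expect_equal(rec$article_id, "PMC0000001")
  expect_length(rec$annotations, 1)
  ann <- rec$annotations[[1]]
  expect_equal(ann$exact, "FastDNA SPIN kit")
  expect_equal(ann$entity_type, "kit")
  expect_lte(nchar(ann$prefix), 30)
  expect_lte(nchar(ann$postfix), 30)
  expect_equal(ann$section, "methods")
  expect_length(ann$tags, 0)

  mapper <- dictionary_mapper(tibble::tibble(
    term = "FastDNA SPIN kit", entity_type = "kit",
    name = "FastDNA", uri = "http://example.org/ENVO_1"
  ))
  rec2 <- emit_annotations(one_kit_doc(), kit_span(), mapper)
  expect_equal(rec2$annotations[[1]]$tags[[1]]$uri, "http://example.org/ENVO_1")
  expect_null(map_term(mapper, "soil", "ecoregion"))
})

test_that("annotation records survive a JSON round trip with stable keys", {
  mapper <- dictionary_mapper(tibble::tibble(
    term = "FastDNA SPIN kit", entity_type = "kit",
    name = "FastDNA", uri = "http://example.org/ENVO_1"
  ))
  rec <- emit_annotations(one_kit_doc(), kit_span(), mapper)
  json <- annotation_record_json(rec)
  expect_identical(annotation_record_json(parse_annotation_record(json)), json)
})

test_that("spans that no longer slice cleanly are an integrity error", {
  bad <- kit_span()
  bad$exact <- "FastDNA SPIN KIT 2"
  expect_error(emit_annotations(one_kit_doc(), bad), "integrity")
  missing <- kit_span()
  missing$sent_id <- "d1:s9:9"
  expect_error(emit_annotations(one_kit_doc(), missing), "unknown sentence")
})

test_that("study XML parsing collects accessions per tag kind", {
  xml <- paste0(
    '<STUDY accession="MGYS1"><STUDY_LINKS>',
    "<ENA-SAMPLE>SRS1</ENA-SAMPLE><ENA-SAMPLE>SRS2</ENA-SAMPLE>",
    "<ENA-RUN>SRR1</ENA-RUN>",
    "</STUDY_LINKS></STUDY>"
  )
  got <- parse_study_xml(xml)
  expect_equal(got$study_id, "MGYS1")
  expect_equal(got$sample_accessions, c("SRS1", "SRS2"))
  expect_equal(got$experiment_accessions, character(0))
  expect_equal(got$run_accessions, "SRR1")

  empty <- parse_study_xml("<STUDY accession='MGYS2'/>")
  expect_equal(empty$sample_accessions, character(0))
  expect_error(parse_study_xml("<STUDY><open"), "malformed")
})

test_that("pooling canonicalizes values and logs unmapped sources", {
  submitted <- tibble::tibble(
    field = c("target gene", "mystery field"),
    value = c("  16S   rRNA ", "x")
  )
  anns <- tibble::tibble(entity_type = c("gene", "gene"),
                         exact = c("16S rRNA", "nifH marker"))
  pools <- pool_metadata(submitted, anns)
  row <- pools[pools$mixs_term == "target_gene", ]
  expect_equal(row$submitted[[1]], "16s rrna")
  expect_setequal(row$annotated[[1]], c("16s rrna", "nifh marker"))
  cov <- attr(pools, "coverage")
  expect_equal(cov$unmapped_fields, "mystery field")

  # idempotence: pooling already-pooled values changes nothing
  again <- pool_metadata(submitted, anns)
  expect_identical(pools$submitted, again$submitted)
  expect_identical(pools$annotated, again$annotated)
})

test_that("unmapped entity types are excluded and counted", {
  mapping <- default_mixs_mapping()
  mapping$mixs_term[mapping$entity_type == "LS"] <- "unmapped"
  pools <- pool_metadata(
    tibble::tibble(field = character(), value = character()),
    tibble::tibble(entity_type = "LS", exact = "amplicon"),
    entity_mapping = mapping
  )
  expect_false("lib_strategy" %in%
                 pools$mixs_term[lengths(pools$annotated) > 0])
  expect_equal(attr(pools, "coverage")$unmapped_entities, "LS")
})

test_that("comparison statuses follow the exact-match rules", {
  pools <- tibble::tibble(
    mixs_term = c("collection_date", "collection_date2", "nucl_acid_ext",
                  "target_gene", "elev"),
    submitted = list("2015", "june 2015", character(0), c("16s", "18s"),
                     character(0)),
    annotated = list("2015", "2015", "rna powersoil total rna isolation kit",
                     c("18s", "its2"), character(0))
  )
  cells <- compare_study(pools)
  expect_equal(cells$status,
               c("identical", "nonidentical", "unique_annotation",
                 "identical", "absent"))
})

test_that("statuses partition and the summary conserves study counts", {
  b <- fx_bundle()
  cells <- compare_studies(b$studies, b$submitted_metadata, b$annotations)
  expect_equal(nrow(cells), nrow(b$studies) *
                 nrow(dplyr::distinct(cells, mixs_term)))
  expect_false(any(duplicated(cells[, c("study_id", "mixs_term")])))
  expect_true(all(cells$status %in% c("identical", "nonidentical",
                                      "unique_submitted", "unique_annotation",
                                      "absent")))
  summary <- summarize_comparison(cells, min_studies_per_field = 0)
  with_data <- cells |>
    dplyr::filter(status != "absent") |>
    dplyr::count(mixs_term, name = "n_total")
  per_term <- summary |>
    dplyr::group_by(mixs_term) |>
    dplyr::summarise(n = sum(n_studies))
  joined <- dplyr::inner_join(with_data, per_term, by = "mixs_term")
  expect_equal(nrow(joined), nrow(with_data))
  expect_equal(joined$n, joined$n_total)
})

test_that("swapping sources only exchanges the unique_* statuses", {
  pools <- tibble::tibble(
    mixs_term = c("a", "b", "c", "d"),
    submitted = list("x", character(0), "y", "z"),
    annotated = list(character(0), "x", "y", "q")
  )
  swapped <- pools
  swapped$submitted <- pools$annotated
  swapped$annotated <- pools$submitted
  c1 <- compare_study(pools)$status
  c2 <- compare_study(swapped)$status
  flip <- c(unique_submitted = "unique_annotation",
            unique_annotation = "unique_submitted")
  expect_equal(ifelse(c1 %in% names(flip), flip[c1], c1), c2,
               ignore_attr = TRUE)
})

test_that("a noise-free bundle compares 100% identical on non-absent cells", {
  clean <- generate_bundle(generator_config(
    seed = 12, metadata_missingness = 0, metadata_inconsistency = 0,
    n_docs_per_class = c("Engineered" = 6, "Environmental" = 6,
                         "Host-associated" = 6)))
  cells <- compare_studies(clean$studies, clean$submitted_metadata,
                           clean$annotations)
  active <- cells$status[cells$status != "absent"]
  expect_gt(length(active), 0)
  expect_true(all(active == "identical"))
})

test_that("missingness surfaces as unique_annotation at the configured rate", {
  noisy <- generate_bundle(generator_config(
    seed = 14, metadata_missingness = 0.3, metadata_inconsistency = 0,
    n_docs_per_class = c("Engineered" = 12, "Environmental" = 12,
                         "Host-associated" = 12)))
  cells <- compare_studies(noisy$studies, noisy$submitted_metadata,
                           noisy$annotations)
  active <- cells |> dplyr::filter(status != "absent")
  expect_equal(sum(active$status == "nonidentical"), 0)
  frac_unique <- mean(active$status == "unique_annotation")
  expect_lt(abs(frac_unique - 0.3), 0.1)
})

test_that("field filtering keeps entity-backed terms and popular submitted fields", {
  cells <- tibble::tibble(
    study_id = paste0("S", 1:10),
    mixs_term = "submitted_only_term",
    status = "unique_submitted"
  )
  mapping <- tibble::tibble(entity_type = "kit", mixs_term = "nucl_acid_ext")
  kept <- summarize_comparison(cells, mapping, min_studies_per_field = 5)
  expect_true("submitted_only_term" %in% kept$mixs_term)
  dropped <- summarize_comparison(cells, mapping, min_studies_per_field = 50)
  expect_false("submitted_only_term" %in% dropped$mixs_term)

  entity_cells <- tibble::tibble(study_id = "S1", mixs_term = "nucl_acid_ext",
                                 status = "unique_annotation")
  expect_true("nucl_acid_ext" %in%
                summarize_comparison(entity_cells, mapping, 50)$mixs_term)
})

test_that("the comparison summary plots as stacked bars", {
  b <- fx_bundle()
  cells <- compare_studies(b$studies, b$submitted_metadata, b$annotations)
  summary <- summarize_comparison(cells, min_studies_per_field = 0)
  p <- ggplot2::ggplot_build(autoplot(summary))
  expect_gt(nrow(p$data[[1]]), 0)
})
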