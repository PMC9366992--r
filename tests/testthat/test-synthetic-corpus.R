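test_that("generation is deterministic under seed and varies across seeds", {
  cfg <- generator_config(seed = 7, n_docs_per_class = c(
    "Engineered" = 3, "Environmental" = 3, "Host-associated" = 3))
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  keep <- setdiff(names(b1), "config")
  expect_identical(b1[keep], b2[keep])

  b3 <- generate_bundle(generator_config(seed = 8, n_docs_per_class = c(
    "Engineered" = 3, "Environmental" = 3, "Host-associated" = 3)))
  expect_false(identical(b1$documents, b3$documents))
})

test_that("config validation rejects bad fractions and empty lexicons", {
  expect_error(generator_config(mixture = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(metadata_missingness = -0.1), "\\[0, 1\\]")
  lex <- default_entity_lexicons()
  lex$kit <- character(0)
  expect_error(generator_config(entity_lexicons = lex), "kit")
  lex$kit <- NULL
  expect_error(generator_config(entity_lexicons = lex), "kit")
})

test_that("per-class document counts match the config", {
  b <- fx_bundle()
  counts <- table(b$biome_labels$class)
  expect_equal(unname(counts[c("Engineered", "Environmental",
                               "Host-associated")]),
               as.table(c(8L, 8L, 8L)), ignore_attr = TRUE)
  expect_false(any(duplicated(b$documents$doc_id)))
})

test_that("documents carry the five canonical sections in order", {
  b <- fx_bundle()
  types <- b$documents$sections[[1]]$canonical_type
  expect_equal(types, c("abstract", "introduction", "methods", "results",
                        "discussion"))
})

test_that("every planted span slices to its exact text", {
  b <- fx_bundle()
  sents <- corpus_sentences(b$documents)
  ann <- b$annotations
  sent_text <- sents$text[match(ann$sent_id, sents$sent_id)]
  expect_false(anyNA(sent_text))
  expect_equal(substring(sent_text, ann$char_start + 1, ann$char_end),
               ann$exact)
})

test_that("entities land predominantly in methods sections", {
  b <- fx_bundle()
  sents <- corpus_sentences(b$documents)
  sec <- sents$canonical_type[match(b$annotations$sent_id, sents$sent_id)]
  expect_true(all(sec == "methods"))
})

test_that("nested site/place plants produce overlapping spans of different types", {
  b <- fx_bundle()
  sites <- b$annotations |> dplyr::filter(entity_type == "site")
  expect_gt(nrow(sites), 0)
  nested <- b$annotations |>
    dplyr::filter(entity_type == "place") |>
    dplyr::semi_join(sites, by = c("sent_id", "char_start"))
  expect_equal(nrow(nested), nrow(sites))
  expect_true(all(nested$char_start >= sites$char_start[
    match(nested$sent_id, sites$sent_id)]))
})

test_that("plant_rate 0 yields zero annotations", {
  b <- generate_bundle(generator_config(
    seed = 3, plant_rate = 0,
    n_docs_per_class = c("Engineered" = 2, "Environmental" = 2,
                         "Host-associated" = 2)))
  expect_equal(nrow(b$annotations), 0)
  expect_equal(sum(truth_report(b)$quantity == "annotations"), 0)
})

test_that("mixture 1 with disjoint vocabularies keeps class token sets disjoint", {
  b <- generate_bundle(generator_config(
    seed = 5, mixture = 1,
    n_docs_per_class = c("Engineered" = 3, "Environmental" = 3,
                         "Host-associated" = 3)))
  cues <- unique(unlist(metamine:::default_section_cues()))
  vocabs <- metamine:::default_class_vocabularies()
  sents <- corpus_sentences(b$documents) |>
    dplyr::filter(canonical_type != "methods") |>
    dplyr::left_join(b$biome_labels, by = "doc_id")
  toks <- sents |>
    dplyr::group_by(class) |>
    dplyr::summarise(tokens = list(setdiff(
      unique(tolower(unlist(strsplit(gsub("\\.", "", text), " ")))), cues
    )))
  for (i in seq_len(nrow(toks))) {
    other <- unlist(vocabs[setdiff(names(vocabs), toks$class[i])])
    expect_length(intersect(toks$tokens[[i]], other), 0)
  }
})

test_that("truth_report counts equal a brute-force recount", {
  b <- fx_bundle()
  rep <- truth_report(b)
  expect_equal(sum(rep$n[rep$quantity == "documents"]), nrow(b$documents))
  for (ty in unique(b$annotations$entity_type)) {
    expect_equal(rep$n[rep$quantity == "annotations" & rep$key == ty],
                 sum(b$annotations$entity_type == ty))
  }
  expect_equal(rep$n[rep$quantity == "studies"], nrow(b$studies))
})

test_that("every study cross-references generated documents of its class", {
  b <- fx_bundle()
  for (i in seq_len(nrow(b$studies))) {
    docs <- b$studies$publication_ids[[i]]
    expect_gte(length(docs), 1)
    cls <- b$biome_labels$class[match(docs, b$biome_labels$doc_id)]
    expect_true(all(cls == b$studies$biome_class[i]))
    expect_equal(b$studies$biome_lineage[[i]][1], b$studies$biome_class[i])
  }
})

test_that("bundle artifacts round-trip through the on-disk formats", {
  b <- fx_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_identical(read_corpus_jsonl(file.path(dir, "corpus.jsonl")),
                   b$documents)
  ann <- read_annotations_jsonl(file.path(dir, "annotations.jsonl"))
  expect_equal(as.data.frame(ann), as.data.frame(b$annotations))
  studies <- read_studies_jsonl(file.path(dir, "studies.jsonl"))
  expect_equal(studies$study_id, b$studies$study_id)
  expect_identical(studies$biome_lineage, b$studies$biome_lineage)
  expect_identical(studies$publication_ids, b$studies$publication_ids)

  one <- parse_study_xml(file.path(dir, "studies_xml",
                                   paste0(b$studies$study_id[1], ".xml")))
  expect_equal(one$study_id, b$studies$study_id[1])
  expect_equal(one$sample_accessions, b$studies$sample_accessions[[1]])
  expect_equal(one$run_accessions, b$studies$run_accessions[[1]])
})
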