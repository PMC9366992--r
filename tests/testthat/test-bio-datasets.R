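test_that("unique occurrences anchor directly and slices match", {
  b <- fx_bundle()
  raw <- b$annotations[, c("doc_id", "exact", "prefix", "suffix",
                           "entity_type")]
  res <- anchor_annotations(b$documents, raw)
  expect_equal(nrow(res$rejects), 0)
  expect_equal(nrow(res$anchored), nrow(b$annotations))
  joined <- dplyr::inner_join(
    res$anchored, b$annotations,
    by = c("doc_id", "sent_id", "entity_type", "exact"),
    suffix = c("", ".gold")
  )
  expect_equal(nrow(joined), nrow(b$annotations))
  expect_equal(joined$char_start, joined$char_start.gold)
  expect_equal(joined$char_end, joined$char_end.gold)
})

test_that("context disambiguates repeated occurrences; failures are reported", {
  doc <- new_document("d1", sections = tibble::tibble(
    heading = "Methods", canonical_type = "methods",
    sentences = list(tibble::tibble(
      sent_id = c("d1:s1:1", "d1:s1:2"),
      text = c("Samples from the gut here.", "Controls from the gut there."),
      char_start = c(0L, 27L), char_end = c(26L, 55L)
    ))
  ))
  raw <- tibble::tibble(
    doc_id = "d1", exact = "gut",
    prefix = "Controls from the ", suffix = " there.",
    entity_type = "body-site"
  )
  res <- anchor_annotations(doc, raw)
  expect_equal(res$anchored$sent_id, "d1:s1:2")

  missing <- tibble::tibble(doc_id = "d1", exact = "liver", prefix = "",
                            suffix = "", entity_type = "body-site")
  expect_equal(anchor_annotations(doc, missing)$rejects$reason,
               "unanchorable")

  ambiguous <- tibble::tibble(doc_id = "d1", exact = "from the", prefix = "",
                              suffix = "", entity_type = "treatment")
  expect_equal(anchor_annotations(doc, ambiguous)$rejects$reason, "ambiguous")
})

test_that("BIO tagging marks span tokens B then I and everything else O", {
  toks <- simple_tokens("Samples were collected from the Namib Desert")
  span <- tibble::tibble(char_start = 32L, char_end = 44L,
                         entity_type = "ecoregion")
  expect_equal(bio_tag(toks, span), c("O", "O", "O", "O", "O", "B", "I"))
  expect_equal(bio_tag(toks, span[0, ]), rep("O", 7))
})

test_that("adjacent spans restart at B and mixed types are rejected", {
  toks <- simple_tokens("alpha beta gamma")
  spans <- tibble::tibble(char_start = c(0L, 6L), char_end = c(5L, 10L),
                          entity_type = "kit")
  expect_equal(bio_tag(toks, spans), c("B", "B", "O"))
  mixed <- tibble::tibble(char_start = c(0L, 6L), char_end = c(5L, 10L),
                          entity_type = c("kit", "gene"))
  expect_error(bio_tag(toks, mixed), "single entity type")
})

test_that("nested site/place pairs tag differently per entity dataset", {
  toks <- simple_tokens("Cores from the Nevada hot springs today")
  site <- tibble::tibble(char_start = 15L, char_end = 33L,
                         entity_type = "site")
  place <- tibble::tibble(char_start = 15L, char_end = 21L,
                          entity_type = "place")
  expect_equal(bio_tag(toks, site)[4:6], c("B", "I", "I"))
  expect_equal(bio_tag(toks, place)[4:6], c("B", "O", "O"))
})

test_that("all 16 datasets share one sentence universe and split", {
  ds <- fx_datasets()
  expect_length(ds, 16)
  expect_setequal(names(ds), entity_types())
  ids <- lapply(ds, function(d) {
    list(train = names(d$train), test = names(d$test))
  })
  for (d in ids[-1]) expect_identical(d, ids[[1]])
  expect_length(intersect(ids[[1]]$train, ids[[1]]$test), 0)
  split <- attr(ds, "split")
  expect_equal(sum(split$split == "train"),
               floor(0.9 * nrow(split)))
})

test_that("sentences are all-O in datasets of absent entity types", {
  b <- fx_bundle()
  ds <- fx_datasets()
  kit_sents <- unique(b$annotations$sent_id[b$annotations$entity_type == "kit"])
  other <- setdiff(entity_types(), "kit")
  sid <- kit_sents[1]
  types_here <- unique(b$annotations$entity_type[b$annotations$sent_id == sid])
  for (ty in setdiff(other, types_here)) {
    tagged <- c(ds[[ty]]$train, ds[[ty]]$test)[[sid]]
    expect_true(all(tagged$tags == "O"))
  }
  kit_tagged <- c(ds$kit$train, ds$kit$test)[[sid]]
  expect_true(any(kit_tagged$tags == "B"))
})

test_that("union of B/I tokens over the 16 datasets equals the annotation token cover", {
  b <- fx_bundle()
  ds <- fx_datasets()
  vocab <- fx_vocab()
  sents <- corpus_sentences(b$documents)
  # recount: tokens covered by any annotation, computed from scratch
  covered <- list()
  for (sid in unique(b$annotations$sent_id)) {
    text <- sents$text[sents$sent_id == sid]
    toks <- wordpiece_tokenize(text, vocab)
    ann <- b$annotations[b$annotations$sent_id == sid, ]
    hit <- rep(FALSE, nrow(toks))
    for (a in seq_len(nrow(ann))) {
      hit <- hit | (toks$char_start < ann$char_end[a] &
                      toks$char_end > ann$char_start[a])
    }
    covered[[sid]] <- which(hit)
  }
  tagged_union <- list()
  for (ty in entity_types()) {
    for (ts in c(ds[[ty]]$train, ds[[ty]]$test)) {
      nz <- which(ts$tags != "O")
      if (length(nz)) {
        tagged_union[[ts$sent_id]] <- sort(union(tagged_union[[ts$sent_id]],
                                                 nz))
      }
    }
  }
  expect_setequal(names(tagged_union), names(covered))
  for (sid in names(covered)) {
    expect_equal(tagged_union[[sid]], covered[[sid]])
  }
})

test_that("no tagged sentence has an I following an O", {
  ds <- fx_datasets()
  for (ty in c("site", "kit", "primer")) {
    for (ts in c(ds[[ty]]$train, ds[[ty]]$test)) {
      tags <- ts$tags
      expect_equal(length(tags), nrow(ts$tokens))
      if (length(tags) > 1) {
        bad <- tags[-1] == "I" & tags[-length(tags)] == "O"
        expect_false(any(bad))
      }
      expect_false(length(tags) > 0 && tags[1] == "I")
    }
  }
})

test_that("truncation keeps max_len tokens and logs unlearnable spans", {
  toks <- simple_tokens(paste(rep("word", 130), collapse = " "))
  tagged <- list(tokens = toks, tags = c(rep("O", 125), "B", "I", "O", "B",
                                         "I"))
  out <- truncate_to_max_len(tagged, 128)
  expect_true(out$truncated)
  expect_equal(nrow(out$tokens), 128)
  expect_length(out$tags, 128)
  expect_equal(out$dropped_spans, 1L)

  exact <- list(tokens = toks[1:128, ], tags = rep("O", 128))
  out2 <- truncate_to_max_len(exact, 128)
  expect_false(out2$truncated)
  expect_equal(nrow(out2$tokens), 128)
})

test_that("annotations outside the schema are rejected by name", {
  b <- fx_bundle()
  bad <- b$annotations[1, ]
  bad$entity_type <- "flavor"
  expect_error(
    build_entity_datasets(b$documents, dplyr::bind_rows(b$annotations, bad)),
    "flavor"
  )
})

test_that("datasets can be written as per-type TSVs", {
  ds <- fx_datasets()
  dir <- withr::local_tempdir()
  write_entity_datasets(ds[c("kit", "gene")], dir)
  tsv <- utils::read.delim(file.path(dir, "kit", "train.tsv"))
  expect_true(all(c("sent_id", "token", "char_start", "char_end", "tag") %in%
                    names(tsv)))
  expect_gt(nrow(tsv), 0)
})
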