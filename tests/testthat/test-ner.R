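test_that("token-wise metrics match hand-computed confusion values", {
  perfect <- evaluate_tokenwise(c("O", "O", "B", "I"), c("O", "O", "B", "I"))
  expect_equal(perfect$macro_precision, 1)
  expect_equal(perfect$macro_recall, 1)
  expect_equal(perfect$macro_f1, 1)

  # gold B I O O O vs pred B O O O O:
  #   B: P=1, R=1, F1=1; I: no predictions -> P=R=F1=0;
  #   O: TP=3, FP=1 -> P=3/4, R=1, F1=6/7
  ev <- evaluate_tokenwise(c("B", "O", "O", "O", "O"),
                           c("B", "I", "O", "O", "O"))
  expect_equal(ev$macro_precision, (1 + 0 + 3 / 4) / 3)
  expect_equal(ev$macro_recall, (1 + 0 + 1) / 3)
  expect_equal(ev$macro_f1, (1 + 0 + 6 / 7) / 3)

  allO <- evaluate_tokenwise(rep("O", 5), c("B", "I", "O", "O", "O"))
  expect_lt(allO$macro_f1, 1)
  expect_equal(allO$report$recall[allO$report$class == "O"], 1)
})

test_that("macro averages only over classes present in the gold", {
  ev <- evaluate_tokenwise(c("O", "B", "O"), c("O", "O", "O"))
  expect_equal(nrow(ev$report), 2) # O plus macro row
  expect_equal(ev$report$class, c("O", "macro avg"))
  expect_error(evaluate_tokenwise(c("O", "O"), c("O")), "mismatch")
  expect_error(evaluate_tokenwise(list(c("O", "O")), list(c("O"))),
               "mismatch")
})

test_that("metric implementation equals brute-force recount on 1000 random pairs", {
  withr::with_seed(23, {
    for (rep in 1:1000) {
      n <- sample(1:30, 1)
      gold <- random_tags(n)
      pred <- random_tags(n)
      ev <- evaluate_tokenwise(pred, gold)
      bf <- brute_force_tokenwise(pred, gold)
      expect_identical(ev$macro_precision, bf$macro_precision)
      expect_identical(ev$macro_recall, bf$macro_recall)
      expect_identical(ev$macro_f1, bf$macro_f1)
    }
  })
})

test_that("span decoding inverts BIO tagging, with I-start repair", {
  toks <- simple_tokens("alpha beta gamma delta eps")
  tagged <- list(tokens = toks, tags = c("O", "O", "B", "I", "O"),
                 text = "alpha beta gamma delta eps")
  spans <- decode_spans(tagged)
  expect_equal(nrow(spans), 1)
  expect_equal(spans$exact, "gamma delta")
  expect_equal(spans$char_start, 11)
  expect_equal(spans$char_end, 22)

  repaired <- decode_spans(list(tokens = toks[1:3, ],
                                tags = c("O", "I", "I"),
                                text = "alpha beta gamma"))
  expect_equal(nrow(repaired), 1)
  expect_equal(repaired$exact, "beta gamma")
  expect_equal(attr(repaired, "repairs"), 1L)
})

test_that("bio_tag then decode_spans recovers span token covers on 1000 random sentences", {
  vocab <- fx_vocab()
  b <- fx_bundle()
  sents <- corpus_sentences(b$documents)
  withr::with_seed(29, {
    for (rep in 1:1000) {
      i <- sample(nrow(sents), 1)
      toks <- wordpiece_tokenize(sents$text[i], vocab)
      n <- nrow(toks)
      if (n < 2) next
      # random non-overlapping token-aligned spans
      k <- sample(1:min(3, n %/% 2), 1)
      starts <- sort(sample(seq_len(n), k))
      spans <- tibble::tibble(
        char_start = toks$char_start[starts],
        char_end = toks$char_end[pmin(starts + sample(0:2, k, TRUE), n)],
        entity_type = "kit"
      )
      spans <- spans[!duplicated(spans$char_start), ]
      # drop overlapping draws
      keep <- c(TRUE, spans$char_start[-1] >
                  spans$char_end[-nrow(spans)])[seq_len(nrow(spans))]
      spans <- spans[keep, ]
      tags <- bio_tag(toks, spans)
      decoded <- decode_spans(list(tokens = toks, tags = tags,
                                   text = sents$text[i]))
      cover_true <- unlist(lapply(seq_len(nrow(spans)), function(s) {
        which(toks$char_start < spans$char_end[s] &
                toks$char_end > spans$char_start[s])
      }))
      cover_decoded <- unlist(lapply(seq_len(nrow(decoded)), function(s) {
        which(toks$char_start < decoded$char_end[s] &
                toks$char_end > decoded$char_start[s])
      }))
      expect_equal(sort(unique(cover_decoded)), sort(unique(cover_true)))
    }
  })
})

test_that("grid search is exhaustive over 35 combinations and breaks ties to fewer epochs", {
  ds <- fx_tiny_kit_dataset()
  gs <- grid_search_labeler(ds, labeler_config(seed = 42))
  expect_equal(nrow(gs$reports), 35)
  expect_equal(nrow(dplyr::distinct(gs$reports, learning_rate, epoch)), 35)
  # ties at the maximum F1 resolve to smallest epochs, then smallest rate
  best_f1 <- max(gs$reports$f1)
  tied <- gs$reports[gs$reports$f1 == best_f1, ]
  expect_equal(gs$best$epochs, min(tied$epoch))
  expect_equal(gs$best$learning_rate,
               min(tied$learning_rate[tied$epoch == min(tied$epoch)]))
  # the selected combination's report equals its entry in the table
  entry <- gs$reports[gs$reports$learning_rate == gs$best$learning_rate &
                        gs$reports$epoch == gs$best$epochs, ]
  expect_equal(gs$best_report$f1, entry$f1)
  expect_equal(gs$best_report$precision, entry$precision)
})

test_that("an all-O training split yields a degenerate all-O predictor", {
  ds <- fx_tiny_kit_dataset()
  blank <- ds
  blank$train <- lapply(ds$train, function(ts) {
    ts$tags <- rep("O", length(ts$tags))
    ts
  })
  lab <- train_labeler(blank, 5e-5, 30)
  expect_true(lab$degenerate)
  preds <- predict_tags(lab, ds$test)
  expect_true(all(unlist(preds) == "O"))
})

test_that("training and prediction are deterministic under a fixed seed", {
  ds <- fx_tiny_kit_dataset()
  l1 <- train_labeler(ds, 3e-5, 30, labeler_config(seed = 7))
  l2 <- train_labeler(ds, 3e-5, 30, labeler_config(seed = 7))
  expect_identical(l1$W, l2$W)
  expect_identical(predict_tags(l1, ds$test), predict_tags(l2, ds$test))
})

test_that("entity labelers recover templated mentions at high macro-F1", {
  panel <- fx_panel()
  expect_equal(nrow(panel$reports), 16)
  expect_setequal(panel$reports$entity, entity_types())
  expect_true(all(panel$reports$f1 >= 0.8))
  expect_gte(mean(panel$reports$f1), 0.8)
  expect_equal(nrow(panel$all_reports), 16 * 35)
  # at the default study scale (~400 templated sentences) the kit labeler
  # exceeds 0.85 comfortably
  study <- fx_study()
  expect_gte(study$teacher_reports$f1[
    study$teacher_reports$entity == "kit"], 0.85)
})

test_that("annotate_document labels methods mentions only, idempotently", {
  b <- fx_bundle()
  panel <- fx_panel()
  vocab <- fx_vocab()
  kit_ann <- b$annotations[b$annotations$entity_type == "kit", ]
  doc_id <- kit_ann$doc_id[1]
  doc <- b$documents[b$documents$doc_id == doc_id, ]

  spans <- annotate_document(doc, panel$labelers, vocab)
  expect_true(all(spans$provenance == "predicted"))
  got_kit <- spans[spans$entity_type == "kit", ]
  want <- kit_ann[kit_ann$doc_id == doc_id, ]
  expect_true(all(want$exact %in% got_kit$exact))

  # annotation is idempotent
  spans2 <- annotate_document(doc, panel$labelers, vocab)
  expect_identical(spans, spans2)

  # spans are methods-scoped: move the methods content into results
  moved <- doc
  secs <- moved$sections[[1]]
  secs$canonical_type[secs$canonical_type == "methods"] <- "results"
  moved$sections[[1]] <- secs
  expect_equal(nrow(annotate_document(moved, panel$labelers, vocab)), 0)

  # a missing labeler is an error
  expect_error(annotate_document(doc, panel$labelers[-1], vocab), "missing")
})

test_that("decoded spans never overlap within one entity type", {
  b <- fx_bundle()
  panel <- fx_panel()
  spans <- annotate_corpus(b$documents[1:4, ], panel$labelers, fx_vocab())
  expect_gt(nrow(spans), 0)
  by_sent <- split(spans, list(spans$sent_id, spans$entity_type), drop = TRUE)
  for (g in by_sent) {
    if (nrow(g) < 2) next
    g <- g[order(g$char_start), ]
    expect_true(all(g$char_start[-1] >= g$char_end[-nrow(g)]))
  }
  expect_true(all(spans$char_end > spans$char_start))
})
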