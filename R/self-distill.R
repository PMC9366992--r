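# Teacher-student self-distillation: teachers (trained on the curated
# corpus) annotate a fresh corpus selected by the biome classifier; student
# labelers are trained from scratch on those predictions only and evaluated
# token-wise against the curated corpus. Students passing the F1 criterion
# indicate that the teachers generalise beyond the curated data.

#' Self-distillation configuration
#'
#' @param biome_prob_threshold Minimum argmax class probability for a
#'   document to qualify for the distillation corpus.
#' @param n_docs_per_class Documents sampled per biome class (the reference
#'   protocol uses 500; the desk-scale default is 60).
#' @param pass_f1_threshold Student pass criterion on token-wise macro-F1.
#' @param seed Integer seed for the per-class sampling.
#' @return An object of class `distill_config`.
#' @export
distill_config <- function(biome_prob_threshold = 0.5, n_docs_per_class = 60,
                           pass_f1_threshold = 0.70, seed = 9) {
  stopifnot(biome_prob_threshold >= 0,
            pass_f1_threshold >= 0, pass_f1_threshold <= 1)
  structure(
    list(
      biome_prob_threshold = biome_prob_threshold,
      n_docs_per_class = as.integer(n_docs_per_class),
      pass_f1_threshold = pass_f1_threshold,
      seed = as.integer(seed)
    ),
    class = "distill_config"
  )
}

#' Select the distillation corpus
#'
#' Classifies every document of a fresh corpus and samples, per class, up
#' to `n_docs_per_class` documents whose argmax probability meets the
#' threshold (without replacement, seeded).
#'
#' @param new_corpus A corpus tibble, disjoint from the gold corpus.
#' @param biome_classifier A `trained_classifier` with a featurizer.
#' @param config A [distill_config()].
#' @param scope Text scope used for classification.
#' @return The selected subset of `new_corpus` (a corpus tibble), with the
#'   triage table attached as attribute `"triage"`.
#' @export
select_distillation_corpus <- function(new_corpus, biome_classifier,
                                       config = distill_config(),
                                       scope = "fulltext") {
  texts <- purrr::map_chr(seq_len(nrow(new_corpus)), function(i) {
    document_text(new_corpus[i, ], scope)
  })
  probs <- predict_proba(biome_classifier, texts)
  probs$doc_id <- new_corpus$doc_id
  # a threshold above 1 is a legitimate degenerate request (empty selection)
  selected <- triage(probs, threshold = min(1, config$biome_prob_threshold)) |>
    filter(.data$prob >= config$biome_prob_threshold)
  sampled <- with_local_seed(config$seed, {
    selected |>
      group_by(.data$class) |>
      slice_sample(n = config$n_docs_per_class) |>
      ungroup()
  })
  short <- sampled |>
    count(.data$class) |>
    filter(.data$n < config$n_docs_per_class)
  if (nrow(short) > 0 || !setequal(unique(selected$class),
                                   biome_classifier$classes)) {
    warning("some classes yielded fewer than ", config$n_docs_per_class,
            " qualifying documents", call. = FALSE)
  }
  out <- new_corpus |> filter(.data$doc_id %in% sampled$doc_id)
  attr(out, "triage") <- sampled
  out
}

#' Run teacher-student self-distillation
#'
#' Teachers annotate the selected corpus; the predictions (provenance
#' `"predicted"` -- students never see a gold label) become the students'
#' training data, with the entire curated corpus as the test set. One
#' student per entity type is trained from scratch with the same grids as
#' the teachers and evaluated token-wise against gold.
#'
#' @param teachers Named list of `sequence_labeler` (one per schema type).
#' @param selection Corpus tibble from [select_distillation_corpus()].
#' @param gold_corpus The curated corpus tibble.
#' @param gold_annotations Anchored curated annotations.
#' @param labeler_cfg A [labeler_config()] for the student grid search.
#' @param config A [distill_config()].
#' @param vocab A `wordpiece_vocab`.
#' @param section_classifier Optional section classifier for methods-text
#'   recovery during teacher annotation.
#' @return A list with `report` (tibble: `entity`, `recall`, `precision`,
#'   `f1`, `pass`), `students` (named list), and `predicted_annotations`.
#' @export
distill <- function(teachers, selection, gold_corpus, gold_annotations,
                    labeler_cfg = labeler_config(),
                    config = distill_config(), vocab = fixture_vocab(),
                    section_classifier = NULL) {
  if (nrow(selection) == 0) stop("empty distillation selection", call. = FALSE)
  overlap <- intersect(selection$doc_id, gold_corpus$doc_id)
  if (length(overlap) > 0) {
    stop("distillation corpus overlaps the gold corpus: ",
         paste(utils::head(overlap, 3), collapse = ", "), call. = FALSE)
  }

  predicted <- annotate_corpus(selection, teachers, vocab, section_classifier)
  if (nrow(predicted) == 0) {
    stop("teachers produced no annotations on the selection", call. = FALSE)
  }
  stopifnot(all(predicted$provenance == "predicted"))

  student_data <- build_entity_datasets(
    selection, predicted, vocab = vocab, seed = labeler_cfg$seed,
    max_len = labeler_cfg$max_len, train_frac = 1
  )
  gold_data <- build_entity_datasets(
    gold_corpus, gold_annotations, vocab = vocab, seed = labeler_cfg$seed,
    max_len = labeler_cfg$max_len, train_frac = 1
  )

  fits <- purrr::map(entity_types(), function(type) {
    grid_search_labeler(student_data[[type]], config = labeler_cfg,
                        eval_sentences = gold_data[[type]]$train)
  })
  names(fits) <- entity_types()

  report <- dplyr::bind_rows(purrr::map(fits, "best_report")) |>
    mutate(pass = .data$f1 >= config$pass_f1_threshold) |>
    select("entity", "recall", "precision", "f1", "pass")

  list(
    report = report,
    students = purrr::map(fits, "best"),
    predicted_annotations = predicted
  )
}
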