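# End-to-end self-distillation study on synthetic corpora: the workflow the
# package exists for, bundled as one call so scripts and tests run the same
# protocol. Teachers are trained on the gold bundle's curated annotations;
# a biome classifier triages a fresh corpus; teachers annotate the
# selection; students train on those predictions only and are evaluated
# token-wise against the full curated corpus.

#' Run the teacher-student distillation study
#'
#' @param seed Integer master seed; the gold bundle, the fresh corpus, and
#'   every model fit derive their seeds from it.
#' @param n_select_per_class Documents selected per biome class for the
#'   distillation corpus.
#' @param n_gold_per_class Documents per class in the gold bundle.
#' @param n_fresh_per_class Documents per class in the fresh corpus (must
#'   comfortably exceed `n_select_per_class`).
#' @param biome_prob_threshold Selection probability threshold.
#' @param pass_f1_threshold Student pass criterion.
#' @param labeler_cfg A [labeler_config()] used for teachers and students.
#' @param forest_g A [forest_grid()] for the biome classifier.
#' @return A list with `teacher_reports`, `student_report`,
#'   `mean_student_f1`, `mean_teacher_f1`, `biome_classifier`, `teachers`,
#'   `students`, `gold`, and `selection`.
#' @export
run_distillation_study <- function(seed = 9,
                                   n_select_per_class = 60,
                                   n_gold_per_class = 20,
                                   n_fresh_per_class = 80,
                                   biome_prob_threshold = 0.5,
                                   pass_f1_threshold = 0.70,
                                   labeler_cfg = labeler_config(seed = seed),
                                   forest_g = forest_grid()) {
  seed <- as.integer(seed) %% 100000L
  vocab <- fixture_vocab()

  per_class <- function(n) {
    stats::setNames(rep(n, 3), biome_classes())
  }
  gold <- generate_bundle(generator_config(
    seed = seed, corpus_label = "G",
    n_docs_per_class = per_class(n_gold_per_class)
  ))
  datasets <- build_entity_datasets(gold$documents, gold$annotations,
                                    vocab = vocab, seed = seed,
                                    max_len = labeler_cfg$max_len)
  panel <- train_labeler_panel(datasets, config = labeler_cfg)

  labeled <- map_labels(gold$studies, gold$documents, level = 1,
                        scope = "fulltext")
  balanced <- balance_dataset(labeled, min_per_class = 5, max_per_class = 100,
                              seed = seed)
  biome_clf <- train_text_classifier(balanced, features = "tfidf",
                                     grid = forest_g, seed = seed,
                                     task = "biome-level-1")

  fresh <- generate_bundle(generator_config(
    seed = seed + 1000L, corpus_label = "F",
    n_docs_per_class = per_class(n_fresh_per_class)
  ))
  dcfg <- distill_config(
    biome_prob_threshold = biome_prob_threshold,
    n_docs_per_class = n_select_per_class,
    pass_f1_threshold = pass_f1_threshold,
    seed = seed
  )
  selection <- select_distillation_corpus(fresh$documents, biome_clf, dcfg)
  result <- distill(panel$labelers, selection, gold$documents,
                    gold$annotations, labeler_cfg = labeler_cfg,
                    config = dcfg, vocab = vocab)

  list(
    teacher_reports = panel$reports,
    student_report = result$report,
    mean_student_f1 = mean(result$report$f1),
    mean_teacher_f1 = mean(panel$reports$f1),
    biome_classifier = biome_clf,
    teachers = panel$labelers,
    students = result$students,
    gold = gold,
    selection = selection
  )
}
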