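#' Pipeline configuration
#'
#' Bundles the constants of the whole train/evaluate workflow: the DEG
#' filter (p < 0.05 and |logFC| > 1, adjusted p by default), the forest
#' stage (500 trees, top 30 genes, Gini importance), the scoring stage
#' (self-medians), and the network (5 hidden nodes, learning rate 0.1).
#'
#' @param sim A [sim_config()] used to simulate the training cohort when no
#'   input files are given, plus test-cohort sizes; or `NULL` when reading
#'   from files.
#' @param train_matrix,train_labels,test_matrix,test_labels Optional input
#'   TSV paths (see [read_expression_set()]).
#' @param n_case_test,n_control_test Simulated test-cohort sizes (5 / 5).
#' @param p_threshold,lfc_threshold,use_adjusted DEG filter settings.
#' @param de_method Differential expression method (see [de_test()]).
#' @param n_trees,k,measure,forest_seed Forest stage settings.
#' @param median_source `"self"` (each cohort uses its own medians) or
#'   `"train"` (training medians transferred to the test cohort).
#' @param n_hidden,lr,max_epochs,tol,ann_seed Network settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            train_matrix = NULL, train_labels = NULL,
                            test_matrix = NULL, test_labels = NULL,
                            n_case_test = 5L, n_control_test = 5L,
                            p_threshold = 0.05, lfc_threshold = 1.0,
                            use_adjusted = TRUE, de_method = "moderated",
                            n_trees = 500L, k = 30L, measure = "gini",
                            forest_seed = 1L, median_source = c("self", "train"),
                            n_hidden = 5L, lr = 0.1, max_epochs = 10000L,
                            tol = 1e-6, ann_seed = 1L) {
  median_source <- match.arg(median_source)
  if (p_threshold <= 0 || lfc_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the training workflow
#'
#' Executes the stages in order — differential expression, DEG filter,
#' 500-tree random forest with out-of-bag error curve, top-k signature,
#' binary gene scoring, network training, training-set ROC — and, when
#' `out_dir` is given, materializes every intermediate as a TSV/JSON
#' artifact plus a JSON run manifest (parameters, seeds, package version,
#' artifact checksums). Reruns with an identical configuration reproduce
#' byte-identical artifacts.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional artifact directory (created if needed).
#' @param train Optional pre-built training [expression_study()]; overrides
#'   both file paths and simulation.
#' @return A `pipeline_bundle` list: `study`, `truth` (simulated runs only),
#'   `deg_table`, `degs`, `forest`, `error_curve`, `optimal_trees`,
#'   `signature`, `scores`, `model`, `train_probs`, `train_roc`,
#'   `train_accuracy`.
#' @export
run_training <- function(cfg, out_dir = NULL, train = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  truth <- NULL
  if (!is.null(train)) {
    study <- train
  } else if (!is.null(cfg$train_matrix)) {
    study <- read_expression_set(cfg$train_matrix, cfg$train_labels)
  } else {
    sim <- simulate_study(cfg$sim)
    study <- sim$study
    truth <- sim$truth
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  deg_table <- stage("diffexpr", de_test(study, method = cfg$de_method))
  degs <- stage("diffexpr", select_degs(deg_table, cfg$p_threshold,
                                        cfg$lfc_threshold, cfg$use_adjusted))
  if (nrow(degs) < cfg$k)
    stop("pipeline stage 'feature_selection': only ", nrow(degs),
         " DEGs pass the filter but k = ", cfg$k,
         " signature genes were requested; lower the thresholds or k",
         call. = FALSE)
  message(sprintf("[diffexpr] %d genes in, %d DEGs out (%s, p < %g, |logFC| > %g)",
                  nrow(deg_table), nrow(degs), cfg$de_method,
                  cfg$p_threshold, cfg$lfc_threshold))

  deg_study <- restrict_genes(study, degs$gene_id)
  forest <- stage("feature_selection",
                  fit_forest(deg_study, cfg$n_trees, cfg$forest_seed))
  curve <- stage("feature_selection", oob_error_curve(forest))
  opt <- optimal_tree_count(curve)
  ranking <- stage("feature_selection", rank_importance(forest, cfg$measure))
  signature <- stage("feature_selection",
                     top_k_signature(ranking, degs, cfg$k))
  message(sprintf("[forest] %d trees, OOB error %.3f at optimum %d trees; top %d signature genes",
                  cfg$n_trees, min(curve$error_overall, na.rm = TRUE), opt,
                  cfg$k))

  scores <- stage("gene_score", score_matrix(study, signature))
  model <- stage("ann", ann_init(cfg$k, cfg$n_hidden, cfg$ann_seed))
  model <- stage("ann", ann_train(model, scores, study$labels,
                                  lr = cfg$lr, max_epochs = cfg$max_epochs,
                                  tol = cfg$tol))
  probs <- stage("ann", predict(model, scores))
  roc <- stage("evaluation", roc_curve(probs, study$labels))
  acc <- accuracy(as.integer(probs > 0.5), study$labels)
  message(sprintf("[ann] %d epochs, final loss %.4g; training AUC %.3f, accuracy %.3f",
                  model$meta$epochs, model$meta$final_loss, roc$auc, acc))

  bundle <- structure(list(
    study = study, truth = truth, deg_table = deg_table, degs = degs,
    forest = forest, error_curve = curve, optimal_trees = opt,
    signature = signature, scores = scores, model = model,
    train_probs = probs, train_roc = roc, train_accuracy = acc,
    config = cfg), class = "pipeline_bundle")

  if (!is.null(out_dir)) write_training_artifacts(bundle, out_dir)
  bundle
}

write_training_artifacts <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_expression_set(bundle$study, p("train_matrix.tsv"),
                       p("train_labels.tsv"))
  write_deg_table(bundle$degs, p("deg_table.tsv"))
  write_tsv(bundle$error_curve, p("oob_error_curve.tsv"))
  write_signature(bundle$signature, p("signature.tsv"))
  write_score_matrix(bundle$scores, p("train_scores.tsv"),
                     p("train_score_medians.tsv"))
  write_ann_model(bundle$model, p("ann_model.json"))
  write_tsv(data.frame(sample_id = names(bundle$train_probs),
                       probability = as.numeric(bundle$train_probs),
                       predicted_class = ifelse(bundle$train_probs > 0.5,
                                                "case", "control"),
                       stringsAsFactors = FALSE),
            p("train_predictions.tsv"))
  write_tsv(data.frame(threshold = bundle$train_roc$thresholds,
                       fpr = bundle$train_roc$fpr,
                       tpr = bundle$train_roc$tpr),
            p("train_roc.tsv"))
  write_manifest(bundle, out_dir)
  invisible(out_dir)
}

write_manifest <- function(bundle, out_dir) {
  cfg <- bundle$config
  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  names(sums) <- files
  cfg_flat <- cfg[!vapply(cfg, is.null, logical(1L))]
  cfg_flat <- lapply(cfg_flat, function(x)
    if (inherits(x, "sim_config")) unclass(x) else x)
  jsonlite::write_json(list(
    package = "sigscoreann",
    version = as.character(utils::packageVersion("sigscoreann")),
    config = cfg_flat,
    seeds = list(simulation = cfg$sim$seed, forest = cfg$forest_seed,
                 ann = cfg$ann_seed),
    n_samples = length(sample_ids(bundle$study)),
    n_genes = n_genes(bundle$study),
    n_degs = nrow(bundle$degs),
    optimal_trees = bundle$optimal_trees,
    training_auc = bundle$train_roc$auc,
    training_accuracy = bundle$train_accuracy,
    artifacts = as.list(sums)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Evaluate a trained pipeline on a test cohort
#'
#' Scores the test samples with the training signature — fold-change signs
#' always come from training; medians come from the test cohort itself
#' unless `median_source = "train"` — then predicts with the trained
#' network and computes ROC, AUC, and accuracy.
#'
#' @param bundle A `pipeline_bundle` from [run_training()].
#' @param test A test [expression_study()] over the same gene universe, or
#'   `NULL` to simulate one paired with the training cohort (simulated runs
#'   only).
#' @param out_dir Optional artifact directory.
#' @return A list: `scores`, `probs`, `predicted`, `roc`, `auc`, `accuracy`.
#' @export
run_test_evaluation <- function(bundle, test = NULL, out_dir = NULL) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  cfg <- bundle$config
  if (is.null(test)) {
    if (!is.null(cfg$test_matrix)) {
      test <- read_expression_set(cfg$test_matrix, cfg$test_labels)
    } else if (!is.null(bundle$truth)) {
      test <- simulate_paired_cohorts(cfg$sim, cfg$n_case_test,
                                      cfg$n_control_test)$test
    } else {
      stop("no test cohort: supply `test` or configure test files",
           call. = FALSE)
    }
  }
  medians <- if (cfg$median_source == "train") bundle$scores$medians else NULL
  scores <- score_matrix(test, bundle$signature, medians = medians)
  probs <- predict(bundle$model, scores)
  predicted <- as.integer(probs > 0.5)
  roc <- roc_curve(probs, test$labels)
  acc <- accuracy(predicted, test$labels)
  message(sprintf("[test] n = %d (%d case / %d control): AUC %.3f, accuracy %.3f",
                  length(test$labels), sum(test$labels == 1L),
                  sum(test$labels == 0L), roc$auc, acc))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_score_matrix(scores, p("test_scores.tsv"),
                       p("test_score_medians.tsv"))
    write_tsv(data.frame(sample_id = names(probs),
                         probability = as.numeric(probs),
                         predicted_class = ifelse(predicted == 1L,
                                                  "case", "control"),
                         stringsAsFactors = FALSE),
              p("test_predictions.tsv"))
    write_tsv(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                         tpr = roc$tpr), p("test_roc.tsv"))
    jsonlite::write_json(
      list(auc = roc$auc, accuracy = acc,
           n_case = sum(test$labels == 1L),
           n_control = sum(test$labels == 0L)),
      p("test_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(scores = scores, probs = probs, predicted = predicted, roc = roc,
       auc = roc$auc, accuracy = acc)
}
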