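#' Run the six-step pipeline end to end
#'
#' Executes: (1) trajectory summarization into AUE/TOE features; (2-3)
#' stratified 80/20 split, grid-search + k-fold CV hyperparameter tuning
#' on the training split, final fit and test-set evaluation with
#' vote-fraction risks; (4) OOB permutation-importance ranking; (5) the
#' cross-validated AUC-versus-q curve and selection of the number of
#' retained features at its flattening point, with a test-set evaluation
#' of the reduced model; (6) PDP and ALE curves for the selected features;
#' plus the per-domain ablation table. Every stage draws a named seed
#' substream from `config$seed`, so results are fully reproducible.
#'
#' By default the importance ranking is computed on the training split
#' only, which protects the held-out AUC; `config$ranking_on = "full"`
#' reproduces a full-data ranking instead (a leakage warning is logged,
#' since the selected features then saw the test outcomes).
#'
#' @param cohort A `longitudinal_cohort`.
#' @param schema An `exposure_schema` (defaults to the cohort's).
#' @param config A [run_config()].
#' @param verbose Log stage progress to stderr.
#' @return Object of class `pipeline_result`.
#' @export
run_pipeline <- function(cohort, schema = cohort$schema, config = run_config(),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[exposomeRF] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed (seed ", config$seed, "): ",
           conditionMessage(e), call. = FALSE))
  }
  say("step 1: summarizing trajectories")
  table <- stage("summarize", summarize_cohort(cohort, schema))
  labels <- as.integer(cohort$outcome[table$subjects])
  x <- table$x
  p <- ncol(x)
  grid <- config$tuning_grid
  if (is.null(grid)) grid <- default_tuning_grid(p)
  q_grid <- config$q_grid
  if (is.null(q_grid))
    q_grid <- unique(pmin(c(1:10, 12, 16, 24, 32, 48, 64, p), p))

  say("steps 2-3: split, tune (", length(grid), " combinations), fit")
  split <- stage("split", stratified_split(labels, config$test_fraction,
                                           substream_seed(config$seed, "split")))
  xtr <- x[split$train, , drop = FALSE]; ytr <- labels[split$train]
  xte <- x[split$test, , drop = FALSE]; yte <- labels[split$test]
  tuned <- stage("tune", tune_forest(xtr, ytr, grid, config$cv_folds,
                                     substream_seed(config$seed, "tune")))
  model <- stage("fit", fit_forest(xtr, ytr, tuned$best,
                                   substream_seed(config$seed, "final_fit")))
  eval_full <- stage("evaluate", evaluate_model(predict_risk(model, xte), yte))
  say(sprintf("  all-feature test AUC %.3f", eval_full$auc))

  say("step 4: permutation importance (ranking on ", config$ranking_on,
      " data)")
  imp_model <- model
  if (config$ranking_on == "full") {
    warning("leakage: importance ranking computed on the full dataset ",
            "(test rows included); held-out AUCs are optimistic")
    imp_model <- stage("fit_full",
                       fit_forest(x, labels, tuned$best,
                                  substream_seed(config$seed, "full_fit")))
  }
  ranking <- stage("importance", permutation_importance(
    imp_model, seed = substream_seed(config$seed, "importance"),
    n_perm = config$n_perm, n_top_displayed = config$n_top_displayed))
  meta <- table$features[match(ranking$feature_id, table$features$feature_id), ]
  ranking$kind <- meta$kind
  ranking$domain <- meta$domain

  say("step 5: q-performance curve over ", length(q_grid), " values")
  q_curve <- stage("q_curve", q_performance_curve(
    xtr, ytr, ranking, tuned$best, q_grid, config$cv_folds,
    substream_seed(config$seed, "q_curve"),
    epsilon = config$flattening_epsilon))
  top_feats <- ranking$feature_id[seq_len(q_curve$selected_q)]
  par_red <- tuned$best
  par_red$mtry <- min(par_red$mtry, length(top_feats))
  reduced <- stage("reduced_fit", fit_forest(
    xtr[, top_feats, drop = FALSE], ytr, par_red,
    substream_seed(config$seed, "reduced_fit")))
  eval_reduced <- stage("evaluate_reduced", evaluate_model(
    predict_risk(reduced, xte[, top_feats, drop = FALSE]), yte))
  say(sprintf("  selected q = %d; reduced-model test AUC %.3f (vs %.3f full)",
              q_curve$selected_q, eval_reduced$auc, eval_full$auc))

  say("step 6: PDP and ALE curves for the top ", length(top_feats),
      " features")
  prevalence <- mean(labels)
  curves <- list()
  for (fid in top_feats) {
    curves[[paste0(fid, ".PDP")]] <- stage("pdp", pdp(
      model, xtr, fid, grid_size = config$pdp_grid_size,
      clip = config$percentile_clip, reference_level = prevalence))
    curves[[paste0(fid, ".ALE")]] <- stage("ale", suppressMessages(ale(
      model, xtr, fid, n_bins = config$ale_bins,
      clip = config$percentile_clip, reference_level = prevalence)))
  }

  say("domain ablation")
  ablation <- stage("ablation", domain_ablation(table, labels, config))

  structure(list(summary_table = table, split = split, tuning = tuned,
                 model = model, evaluation_full = eval_full,
                 ranking = ranking, q_curve = q_curve,
                 reduced_model = reduced, evaluation_reduced = eval_reduced,
                 effect_curves = curves, ablation = ablation,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Six-step pipeline result\n")
  cat(sprintf("  features: %d; train/test: %d/%d\n",
              ncol(x$summary_table$x), length(x$split$train),
              length(x$split$test)))
  cat(sprintf("  all-feature test AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$evaluation_full$auc, x$evaluation_full$auc_ci["low"],
              x$evaluation_full$auc_ci["high"]))
  cat(sprintf("  selected q = %d; reduced-model test AUC %.3f\n",
              x$q_curve$selected_q, x$evaluation_reduced$auc))
  cat(sprintf("  ablation rows: %d; effect curves: %d\n",
              nrow(x$ablation), length(x$effect_curves)))
  invisible(x)
}
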