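#' Read and validate a longitudinal cohort
#'
#' The cohort file is long-format CSV with header
#' `subject_id,exposure_id,round,value`: one row per subject x exposure x
#' round actually observed. Missing rounds are simply absent (rows whose
#' value is empty or `NA` are treated as absent). The outcome file is CSV
#' `subject_id,label` with label 1 = poor/fair health (the predicted,
#' positive class) and 0 = good health; every subject appearing in the
#' cohort must carry an outcome label.
#'
#' @param cohort_path Path to the long-format exposure CSV.
#' @param outcome_path Path to the outcome CSV.
#' @param schema_path Path to the schema YAML/JSON (see [read_schema()]).
#' @param outcome_round Round index at which the outcome was assessed
#'   (stored, never among the exposure rounds).
#'
#' @return An object of class `longitudinal_cohort`: list with `subjects`,
#'   `records` (data.frame), `outcome` (named 0/1 integer vector),
#'   `outcome_round`, and the `schema`.
#' @export
read_cohort <- function(cohort_path, outcome_path, schema_path,
                        outcome_round = NULL) {
  schema <- if (inherits(schema_path, "exposure_schema")) schema_path
            else read_schema(schema_path)
  rec <- utils::read.csv(cohort_path, colClasses = "character",
                         check.names = FALSE)
  need <- c("subject_id", "exposure_id", "round", "value")
  if (!all(need %in% names(rec)))
    stop("cohort error: cohort CSV must have columns ",
         paste(need, collapse = ","))
  out <- utils::read.csv(outcome_path, colClasses = "character")
  if (!all(c("subject_id", "label") %in% names(out)))
    stop("cohort error: outcome CSV must have columns subject_id,label")
  outcome <- as.integer(out$label)
  if (any(is.na(outcome)) || !all(outcome %in% c(0L, 1L)))
    stop("cohort error: outcome labels must be 0 (good) or 1 (poor/fair)")
  names(outcome) <- out$subject_id
  if (anyDuplicated(out$subject_id))
    stop("cohort error: duplicate subject in outcome table")
  validate_records(rec, schema, outcome, outcome_round)
}

# Shared validation used by read_cohort() and the synthetic generator.
validate_records <- function(rec, schema, outcome, outcome_round = NULL) {
  rec$row <- seq_len(nrow(rec))
  # empty-value / NA rows are "not observed"
  absent <- is.na(rec$value) | rec$value == "" | rec$value == "NA"
  rec <- rec[!absent, , drop = FALSE]
  unknown <- setdiff(unique(rec$exposure_id), names(schema))
  if (length(unknown) > 0L)
    stop("schema error: unknown exposure_id: ",
         paste(unknown, collapse = ", "))
  rec$round <- suppressWarnings(as.integer(rec$round))
  if (any(is.na(rec$round)))
    stop("cohort error: non-integer round at row ",
         rec$row[which(is.na(rec$round))[1L]])
  key <- paste(rec$subject_id, rec$exposure_id, rec$round, sep = "\r")
  if (anyDuplicated(key)) {
    d <- rec$row[duplicated(key)][1L]
    stop("duplication error: duplicate (subject, exposure, round) at row ", d)
  }
  rec$value_num <- NA_real_
  for (eid in unique(rec$exposure_id)) {
    e <- schema[[eid]]
    i <- which(rec$exposure_id == eid)
    bad_round <- !(rec$round[i] %in% e$rounds_measured)
    if (any(bad_round))
      stop("cohort error: exposure '", eid, "' observed in round ",
           rec$round[i][bad_round][1L], " not in rounds_measured (row ",
           rec$row[i][bad_round][1L], ")")
    if (e$var_type == "continuous") {
      v <- suppressWarnings(as.numeric(rec$value[i]))
      if (any(is.na(v)))
        stop("value error: non-numeric value for continuous exposure '", eid,
             "' at row ", rec$row[i][which(is.na(v))[1L]])
      rec$value_num[i] <- v
    } else {
      bad <- !(rec$value[i] %in% e$categories)
      if (any(bad))
        stop("value error: value '", rec$value[i][bad][1L],
             "' not among categories of '", eid, "' at row ",
             rec$row[i][bad][1L])
    }
  }
  subjects <- sort(unique(c(rec$subject_id, names(outcome))))
  missing_out <- setdiff(unique(rec$subject_id), names(outcome))
  if (length(missing_out) > 0L)
    stop("completeness error: subject(s) without outcome label: ",
         paste(utils::head(missing_out, 5L), collapse = ", "))
  subjects <- names(outcome)  # cohort = subjects with complete outcome
  rec <- rec[order(rec$subject_id, rec$exposure_id, rec$round), , drop = FALSE]
  rownames(rec) <- NULL
  if (!is.null(outcome_round)) {
    exp_rounds <- unique(unlist(lapply(schema, `[[`, "rounds_measured")))
    if (outcome_round %in% exp_rounds)
      stop("cohort error: outcome_round ", outcome_round,
           " appears among exposure rounds")
  }
  structure(list(subjects = subjects,
                 records = rec[, c("subject_id", "exposure_id", "round",
                                   "value", "value_num")],
                 outcome = outcome[subjects],
                 outcome_round = outcome_round,
                 schema = schema),
            class = "longitudinal_cohort")
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat("Longitudinal cohort:", length(x$subjects), "subjects,",
      length(x$schema), "exposures,", nrow(x$records), "records;",
      "outcome prevalence", round(mean(x$outcome), 3), "\n")
  invisible(x)
}

#' Write a cohort to long-format CSV (plus outcome CSV)
#'
#' Inverse of [read_cohort()]; missing observations are represented by
#' absence, never by sentinel rows.
#'
#' @param cohort A `longitudinal_cohort`.
#' @param cohort_path,outcome_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, cohort_path, outcome_path) {
  utils::write.csv(cohort$records[, c("subject_id", "exposure_id",
                                      "round", "value")],
                   cohort_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(subject_id = names(cohort$outcome),
                              label = unname(cohort$outcome)),
                   outcome_path, row.names = FALSE, quote = FALSE)
  invisible(c(cohort_path, outcome_path))
}

#' Pipeline run configuration
#'
#' Collects every tunable of the six-step pipeline in one object.
#'
#' @param test_fraction Held-out test proportion (default 0.2, i.e. the
#'   80/20 split).
#' @param cv_folds Folds for every cross-validation (default 5).
#' @param tuning_grid List of [rf_params()] combinations; `NULL` means the
#'   default grid built from the feature count (see [default_tuning_grid()]).
#' @param q_grid Integer vector of candidate numbers of top-ranked features;
#'   `NULL` means a log-spaced default up to p.
#' @param flattening_epsilon AUC tolerance for declaring the q-curve flat
#'   (default 0.005): the smallest q within epsilon of the curve maximum is
#'   selected.
#' @param pdp_grid_size Grid points for partial dependence curves.
#' @param ale_bins Quantile bins for accumulated local effects curves.
#' @param percentile_clip Low/high percentile window for effect-curve grids
#'   (default 5th-95th).
#' @param n_top_displayed Number of features shown in the importance ranking.
#' @param ranking_on `"train"` (default; importance computed on the training
#'   split only, protecting the held-out AUC) or `"full"` (importance refit
#'   on the entire dataset; logged as a leakage warning).
#' @param ablation_retune Re-tune hyperparameters for each domain-ablated
#'   model (default `TRUE`).
#' @param n_perm Permutation repeats per feature for importance.
#' @param seed Master seed; every stage derives a named substream from it.
#'
#' @return Object of class `run_config`.
#' @export
run_config <- function(test_fraction = 0.2, cv_folds = 5L,
                       tuning_grid = NULL, q_grid = NULL,
                       flattening_epsilon = 0.005, pdp_grid_size = 50L,
                       ale_bins = 20L, percentile_clip = c(0.05, 0.95),
                       n_top_displayed = 30L, ranking_on = c("train", "full"),
                       ablation_retune = TRUE, n_perm = 1L, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, cv_folds >= 2,
            length(percentile_clip) == 2L,
            percentile_clip[1] < percentile_clip[2])
  ranking_on <- match.arg(ranking_on)
  structure(list(test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 tuning_grid = tuning_grid, q_grid = q_grid,
                 flattening_epsilon = flattening_epsilon,
                 pdp_grid_size = as.integer(pdp_grid_size),
                 ale_bins = as.integer(ale_bins),
                 percentile_clip = percentile_clip,
                 n_top_displayed = as.integer(n_top_displayed),
                 ranking_on = ranking_on,
                 ablation_retune = isTRUE(ablation_retune),
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "run_config")
}

# Deterministic stage-named substream: every source of randomness in the
# pipeline draws its seed from the master seed plus a stage name, so any
# stage is reproducible in isolation. Kept below 2^31.
substream_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1009021
  as.integer((as.numeric(seed) * 2017 + h * 7919) %% 2147483629)
}

#' Write all pipeline result tables plus a manifest
#'
#' Emits CSV tables (summary feature table, importance ranking, q-curve,
#' effect-curve grids, evaluation report, domain-ablation table - whichever
#' are present in `result`) and a JSON manifest recording the configuration,
#' seed and an MD5 checksum per file.
#'
#' @param result A `pipeline_result` from [run_pipeline()] (or any list with
#'   a compatible subset of fields).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L)
    stop("I/O error: directory not writable: ", out_dir)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 12))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    files <<- c(files, name)
  }
  if (!is.null(result$summary_table))
    wr(as.data.frame(result$summary_table), "summary_features.csv")
  if (!is.null(result$tuning))
    wr(as.data.frame(result$tuning), "tuning.csv")
  if (!is.null(result$ranking))
    wr(as.data.frame(result$ranking), "importance_ranking.csv")
  if (!is.null(result$q_curve) && length(result$q_curve$q_values) > 0L)
    wr(as.data.frame(result$q_curve), "q_curve.csv")
  if (!is.null(result$evaluation_full))
    wr(as.data.frame(result$evaluation_full), "evaluation_full.csv")
  if (!is.null(result$evaluation_reduced))
    wr(as.data.frame(result$evaluation_reduced), "evaluation_reduced.csv")
  if (!is.null(result$effect_curves) && length(result$effect_curves) > 0L)
    wr(do.call(rbind, lapply(result$effect_curves, as.data.frame)),
       "effect_curves.csv")
  if (!is.null(result$ablation))
    wr(result$ablation, "domain_ablation.csv")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(package = "exposomeRF",
                   seed = result$config$seed,
                   config = result$config[setdiff(names(result$config),
                                                  "tuning_grid")],
                   files = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
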