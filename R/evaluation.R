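#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, with ties counted 1/2 (computed from midranks, so it
#' equals trapezoidal ROC integration).
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined-metric error: both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' DeLong confidence interval for the AUC
#'
#' Variance from the positive/negative placement values (DeLong's
#' structural components), normal-approximation interval truncated to
#' `[0, 1]`.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("undefined-metric error: each class needs >= 2 members for the CI")
  auc <- roc_auc(scores, labels)
  # placement of each positive among negatives and vice versa
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  v <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- auc + c(-1, 1) * z * sqrt(v)
  c(low = max(0, ci[1]), high = min(1, ci[2]))
}

#' Optimal ROC threshold (Youden)
#'
#' Scans all midpoints between adjacent distinct scores (plus below-min and
#' above-max boundaries); a subject is called positive when its score
#' exceeds the threshold. Returns the threshold maximizing
#' sensitivity + specificity; ties are broken toward the smallest
#' threshold (favoring sensitivity).
#'
#' @inheritParams roc_auc
#' @return Named vector `c(threshold, sensitivity, specificity)`.
#' @export
optimal_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("undefined-metric error: both classes required")
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  best <- NULL
  for (t in cand) {
    pred <- scores > t
    sens <- sum(pred & labels == 1L) / n_pos
    spec <- sum(!pred & labels == 0L) / n_neg
    if (is.null(best) || sens + spec > best[2] + best[3] + 1e-12)
      best <- c(threshold = t, sensitivity = sens, specificity = spec)
  }
  best
}

#' Sensitivity, specificity and accuracy at a fixed cut-off
#'
#' A subject is called positive when its score is at or above the cut-off
#' (default 0.5, the predefined point).
#'
#' @inheritParams roc_auc
#' @param cutoff Risk cut-off.
#' @return Named vector `c(sensitivity, specificity, accuracy)`.
#' @export
threshold_metrics <- function(scores, labels, cutoff = 0.5) {
  labels <- as.integer(labels)
  pred <- scores >= cutoff
  c(sensitivity = sum(pred & labels == 1L) / sum(labels == 1L),
    specificity = sum(!pred & labels == 0L) / sum(labels == 0L),
    accuracy = mean(pred == (labels == 1L)))
}

#' Calibration-in-the-large
#'
#' Compares the mean predicted risk with the observed outcome prevalence.
#'
#' @inheritParams roc_auc
#' @return Named vector `c(mean_predicted, prevalence, difference)`.
#' @export
calibration_in_the_large <- function(scores, labels) {
  stopifnot(length(scores) > 0L)
  m <- mean(scores); p <- mean(as.integer(labels))
  c(mean_predicted = m, prevalence = p, difference = m - p)
}

#' Decile calibration curve
#'
#' Bins subjects by quantile deciles of the predicted risk (duplicate
#' quantile edges merged) and reports mean predicted risk vs observed
#' outcome fraction per bin.
#'
#' @inheritParams roc_auc
#' @param n_bins Number of quantile bins (default 10).
#' @return Data frame with `bin`, `mean_predicted`, `observed_fraction`, `n`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  stopifnot(length(scores) > 0L)
  labels <- as.integer(labels)
  edges <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(edges) < 2L)  # constant scores: one merged bin
    return(data.frame(bin = 1L, mean_predicted = mean(scores),
                      observed_fraction = mean(labels), n = length(scores)))
  bin <- cut(scores, breaks = edges, include.lowest = TRUE, labels = FALSE)
  data.frame(bin = sort(unique(bin)),
             mean_predicted = as.numeric(tapply(scores, bin, mean)),
             observed_fraction = as.numeric(tapply(labels, bin, mean)),
             n = as.integer(table(bin)))
}

#' Full evaluation report
#'
#' Discrimination (AUC with DeLong 95% CI), the optimal ROC threshold with
#' its sensitivity/specificity, metrics at the predefined 0.5 cut-off,
#' calibration-in-the-large, and the decile calibration curve.
#'
#' @inheritParams roc_auc
#' @param n_bins Calibration bins.
#' @return Object of class `evaluation_report`.
#' @export
evaluate_model <- function(scores, labels, n_bins = 10L) {
  opt <- optimal_threshold(scores, labels)
  at_half <- threshold_metrics(scores, labels, 0.5)
  cal <- calibration_in_the_large(scores, labels)
  structure(list(auc = roc_auc(scores, labels),
                 auc_ci = auc_ci(scores, labels),
                 optimal_threshold = unname(opt["threshold"]),
                 sens_at_optimal = unname(opt["sensitivity"]),
                 spec_at_optimal = unname(opt["specificity"]),
                 sens_spec_sum = unname(opt["sensitivity"] + opt["specificity"]),
                 sens_at_half = unname(at_half["sensitivity"]),
                 spec_at_half = unname(at_half["specificity"]),
                 accuracy_at_half = unname(at_half["accuracy"]),
                 mean_predicted_risk = unname(cal["mean_predicted"]),
                 observed_prevalence = unname(cal["prevalence"]),
                 calibration_bins = calibration_curve(scores, labels, n_bins),
                 n = length(scores)),
            class = "evaluation_report")
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(auc = x$auc, auc_ci_low = x$auc_ci["low"],
             auc_ci_high = x$auc_ci["high"],
             optimal_threshold = x$optimal_threshold,
             sens_at_optimal = x$sens_at_optimal,
             spec_at_optimal = x$spec_at_optimal,
             sens_spec_sum = x$sens_spec_sum,
             accuracy_at_half = x$accuracy_at_half,
             sens_at_half = x$sens_at_half,
             spec_at_half = x$spec_at_half,
             mean_predicted_risk = x$mean_predicted_risk,
             observed_prevalence = x$observed_prevalence,
             n = x$n, row.names = NULL)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), n = %d\n", x$auc,
              x$auc_ci["low"], x$auc_ci["high"], x$n))
  cat(sprintf("optimal threshold %.3f: sens %.3f, spec %.3f\n",
              x$optimal_threshold, x$sens_at_optimal, x$spec_at_optimal))
  cat(sprintf("at 0.5: sens %.3f, spec %.3f, accuracy %.3f\n",
              x$sens_at_half, x$spec_at_half, x$accuracy_at_half))
  cat(sprintf("calibration-in-the-large: mean risk %.3f vs prevalence %.3f\n",
              x$mean_predicted_risk, x$observed_prevalence))
  invisible(x)
}

#' Domain ablation
#'
#' Refits and evaluates the model once with all features and once per
#' exposure domain with that domain's features removed, on the same
#' stratified split and seed, mirroring a "models without a particular
#' domain" comparison table. Each ablated model is re-tuned over the same
#' grid by default.
#'
#' @param table A `summary_features` object.
#' @param labels 0/1 outcome vector aligned with `table$subjects`.
#' @param config A [run_config()].
#' @return Data frame: one evaluation row per model (total + one per
#'   domain present).
#' @export
domain_ablation <- function(table, labels, config) {
  domains <- c("demographic", "lifestyle", "environmental", "biological")
  domains <- unique(c(intersect(domains, table$features$domain),
                      setdiff(unique(table$features$domain), domains),
                      setdiff(domains, table$features$domain)))
  models <- c("total", paste0("without_", domains))
  drop_sets <- c(list(character(0)), lapply(domains, function(d)
    table$features$feature_id[table$features$domain == d]))
  split <- stratified_split(labels, config$test_fraction,
                            substream_seed(config$seed, "split"))
  rows <- vector("list", length(models))
  tuned_total <- NULL
  for (i in seq_along(models)) {
    keep <- setdiff(colnames(table$x), drop_sets[[i]])
    if (length(keep) == 0L)
      stop("empty-model error: ablating domain leaves no features")
    x <- table$x[, keep, drop = FALSE]
    grid <- config$tuning_grid
    if (is.null(grid)) grid <- default_tuning_grid(ncol(x))
    grid <- lapply(grid, function(p) {
      p$mtry <- min(p$mtry, ncol(x)); p })
    if (i == 1L || config$ablation_retune) {
      tuned <- tune_forest(x[split$train, , drop = FALSE],
                           labels[split$train], grid, config$cv_folds,
                           substream_seed(config$seed, "tune"))
      if (i == 1L) tuned_total <- tuned
    } else {
      tuned <- tuned_total
      tuned$best$mtry <- min(tuned$best$mtry, ncol(x))
    }
    m <- fit_forest(x[split$train, , drop = FALSE], labels[split$train],
                    tuned$best, substream_seed(config$seed, "final_fit"))
    ev <- evaluate_model(predict_risk(m, x[split$test, , drop = FALSE]),
                         labels[split$test])
    rows[[i]] <- cbind(data.frame(model = models[i],
                                  n_features = length(keep)),
                       as.data.frame(ev))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
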