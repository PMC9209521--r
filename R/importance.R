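#' Out-of-bag permutation importance (mean decrease in accuracy)
#'
#' For every feature, each tree's classification accuracy on its own
#' out-of-bag subjects is compared with the accuracy on the same subjects
#' after the feature's column has been permuted; the raw (unscaled) mean of
#' these per-tree accuracy drops is the feature's MDA. A fresh permutation
#' of the column is drawn for every repeat and evaluated per tree on its
#' OOB rows (trees differ in their OOB sets, so effective permutations
#' differ across trees). A feature the ensemble never splits on - e.g. a
#' constant column - has MDA exactly 0.
#'
#' @param model A `forest_model` (importance is computed against the
#'   model's own training data, OOB-wise).
#' @param x,labels Must match the model's training data; defaults to them.
#' @param seed Integer seed for the permutations.
#' @param n_perm Permutation repeats per feature (default 1, the classic
#'   single-permutation scheme; raise to reduce Monte-Carlo variance).
#' @param n_top_displayed Features shown by `print()` (default 30).
#' @return Object of class `importance_ranking`: data frame sorted by
#'   descending MDA (ties broken by feature id) with attributes.
#' @export
permutation_importance <- function(model, x = model$training_x,
                                   labels = model$training_labels,
                                   seed = 1L, n_perm = 1L,
                                   n_top_displayed = 30L) {
  x <- as.matrix(x)
  if (!identical(dim(x), dim(model$training_x)) ||
      !isTRUE(all.equal(unname(x), unname(model$training_x))) ||
      !identical(as.integer(labels), model$training_labels))
    stop("contract error: importance must be computed on the model's own training data")
  n <- nrow(x); p <- ncol(x)
  oob <- model$oob
  votes <- tree_votes(model, x)              # n x ntree
  y <- as.integer(labels)
  correct <- votes == matrix(y, n, ncol(votes))
  oob_n <- colSums(oob)
  base_acc <- colSums(correct & oob) / oob_n  # per-tree OOB accuracy
  set.seed(as.integer(seed))
  mda <- numeric(p)
  for (j in seq_len(p)) {
    if (length(unique(x[, j])) == 1L) { mda[j] <- 0; next }
    drops <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      xp <- x
      xp[, j] <- x[sample.int(n), j]
      vp <- tree_votes(model, xp)
      perm_acc <- colSums((vp == matrix(y, n, ncol(vp))) & oob) / oob_n
      drops[r] <- mean(base_acc - perm_acc)
    }
    mda[j] <- mean(drops)
  }
  ord <- order(-mda, colnames(x))
  out <- data.frame(rank = seq_len(p),
                    feature_id = colnames(x)[ord],
                    mda = mda[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("importance_ranking", "data.frame"),
            permutation_seed = as.integer(seed),
            n_perm = as.integer(n_perm),
            n_top_displayed = as.integer(n_top_displayed))
}

#' @export
print.importance_ranking <- function(x, ...) {
  k <- min(attr(x, "n_top_displayed"), nrow(x))
  cat("Permutation importance (raw mean decrease in accuracy), top", k,
      "of", nrow(x), "features:\n")
  print.data.frame(utils::head(x, k), row.names = FALSE)
  invisible(x)
}

#' Cross-validated AUC as a function of the number of retained features
#'
#' Treats the number of top-ranked features q as an additional tuning
#' parameter: for each candidate q, the model is restricted to the top-q
#' features of the ranking (mtry re-capped at min(mtry, q)) and its k-fold
#' CV AUC is computed with the previously selected hyperparameters, on the
#' same fold assignment for every q.
#'
#' @param x,labels Training features and 0/1 labels.
#' @param ranking An `importance_ranking`.
#' @param params The previously tuned [rf_params()].
#' @param q_grid Increasing integer vector of candidate q, within `[1, p]`.
#' @param folds CV folds.
#' @param seed Integer seed.
#' @param epsilon Flattening tolerance handed to [select_q()].
#' @return Object of class `q_curve` with `q_values`, `cv_auc`,
#'   `selected_q` and `epsilon`.
#' @export
q_performance_curve <- function(x, labels, ranking, params, q_grid, folds,
                                seed, epsilon = 0.005) {
  x <- as.matrix(x)
  q_grid <- sort(unique(as.integer(q_grid)))
  if (any(q_grid < 1L) || any(q_grid > ncol(x)))
    stop("parameter error: q_grid must lie in [1, ", ncol(x), "]")
  fold <- stratified_folds(labels, folds, substream_seed(seed, "q_folds"))
  cv_auc <- vapply(q_grid, function(q) {
    feats <- ranking$feature_id[seq_len(q)]
    par <- params; par$mtry <- min(par$mtry, q)
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_forest(x[tr, feats, drop = FALSE], labels[tr], par,
                      seed = substream_seed(seed, paste("qfit", q, f)))
      roc_auc(predict_risk(m, x[!tr, feats, drop = FALSE]), labels[!tr])
    }, numeric(1)))
  }, numeric(1))
  curve <- structure(list(q_values = q_grid, cv_auc = cv_auc,
                          epsilon = epsilon, selected_q = NA_integer_),
                     class = "q_curve")
  curve$selected_q <- select_q(curve, epsilon)
  curve
}

#' Select q at the flattening point of the AUC curve
#'
#' Operationalizes "the curve flattens" as: the smallest q whose CV AUC is
#' within `epsilon` of the curve maximum. The full curve is always kept so
#' the choice can be overridden by eye.
#'
#' @param curve A `q_curve`.
#' @param epsilon AUC tolerance (default 0.005).
#' @return Selected q (integer).
#' @export
select_q <- function(curve, epsilon = 0.005) {
  stopifnot(length(curve$q_values) > 0L)
  ok <- curve$cv_auc >= max(curve$cv_auc) - epsilon
  curve$q_values[which(ok)[1L]]
}

#' @export
as.data.frame.q_curve <- function(x, ...) {
  data.frame(q = x$q_values, cv_auc = x$cv_auc,
             selected = x$q_values == x$selected_q)
}

#' @export
print.q_curve <- function(x, ...) {
  cat("q-performance curve (", length(x$q_values), " points), selected q = ",
      x$selected_q, " (epsilon = ", x$epsilon, ")\n", sep = "")
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
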