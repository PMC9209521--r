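#' Random-forest hyperparameter combination
#'
#' The four tuning parameters of the classification forest: the number of
#' features sampled at each split (`mtry`), the number of trees (`ntree`),
#' the minimum number of observations in terminal nodes (`nodesize`) and
#' the maximum number of terminal nodes (`maxnodes`, `Inf` = unbounded).
#'
#' @param mtry,ntree,nodesize Positive integers.
#' @param maxnodes Integer >= 2, or `Inf` for unbounded trees.
#' @return Object of class `rf_params`.
#' @export
rf_params <- function(mtry, ntree = 500L, nodesize = 1L, maxnodes = Inf) {
  stopifnot(mtry >= 1, ntree >= 1, nodesize >= 1,
            is.infinite(maxnodes) || maxnodes >= 2)
  structure(list(mtry = as.integer(mtry), ntree = as.integer(ntree),
                 nodesize = as.integer(nodesize), maxnodes = maxnodes),
            class = "rf_params")
}

#' Default hyperparameter tuning grid
#'
#' Grid over mtry in {floor(sqrt(p)), floor(p/5), floor(p/3)}, ntree in
#' {500, 1000}, nodesize in {1, 5, 10} and maxnodes in {unbounded, 64, 256};
#' fully overridable via [run_config()].
#'
#' @param p Number of features.
#' @return List of [rf_params()] combinations.
#' @export
default_tuning_grid <- function(p) {
  mtrys <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 5), floor(p / 3))))
  grid <- expand.grid(mtry = mtrys, ntree = c(500L, 1000L),
                      nodesize = c(1L, 5L, 10L), maxnodes = c(Inf, 64, 256))
  lapply(seq_len(nrow(grid)), function(i)
    rf_params(grid$mtry[i], grid$ntree[i], grid$nodesize[i], grid$maxnodes[i]))
}

#' Stratified train/test split
#'
#' Splits subjects into training and test sets with (near-)identical class
#' proportions: per class, `round(n_class * test_fraction)` subjects go to
#' the test set, clamped so that both splits keep at least one member of
#' each class. Deterministic given the seed.
#'
#' @param labels Binary 0/1 vector.
#' @param test_fraction Test proportion in (0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- as.integer(labels)
  if (min(table(factor(labels, levels = 0:1))) < 2L)
    stop("stratification error: each class needs >= 2 members")
  test <- integer(0)
  set.seed(as.integer(seed))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    k <- round(length(idx) * test_fraction)
    k <- min(max(k, 1L), length(idx) - 1L)  # keep each class in both splits
    test <- c(test, sample(idx, k))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

# Stratified k-fold assignment; same folds reused across grid combinations.
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  set.seed(as.integer(seed))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k))
    if (length(unique(labels[fold != f])) < 2L ||
        length(unique(labels[fold == f])) < 2L)
      stop("fold-construction error: fold ", f, " has a single class")
  fold
}

#' Fit a classification random forest
#'
#' Wraps the classic bagged-tree ensemble: each tree is grown on a
#' bootstrap sample with `mtry` candidate features per split, honoring
#' `nodesize` and `maxnodes`; out-of-bag membership per tree is recorded
#' for honest accuracy and permutation importance. Training data are kept
#' on the model for OOB computations.
#'
#' @param x Numeric matrix (subjects x features) without missing entries.
#' @param labels Binary 0/1 vector (1 = positive/poor-health class).
#' @param params An [rf_params()] combination.
#' @param seed Integer seed.
#' @return Object of class `forest_model`.
#' @export
fit_forest <- function(x, labels, params, seed) {
  x <- as.matrix(x)
  if (params$mtry > ncol(x))
    stop("parameter error: mtry (", params$mtry, ") exceeds feature count (",
         ncol(x), ")")
  if (anyNA(x)) stop("contract violation: missing entries in features")
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = params$ntree, mtry = params$mtry,
    nodesize = params$nodesize,
    maxnodes = if (is.infinite(params$maxnodes)) NULL else params$maxnodes,
    keep.inbag = TRUE, keep.forest = TRUE)
  oob <- rf$inbag == 0L  # n x ntree: TRUE where subject is out-of-bag
  cov <- mean(rowSums(oob) > 0)
  if (cov < 0.99)
    warning("OOB coverage ", round(cov, 3), " < 0.99; increase ntree")
  structure(list(rf = rf, params = params,
                 feature_ids = colnames(x), oob = oob,
                 training_x = x, training_labels = as.integer(labels),
                 training_seed = as.integer(seed)),
            class = "forest_model")
}

#' Predicted risk as the vote fraction
#'
#' The predicted probability of the positive class is the proportion of
#' trees whose hard class vote is 1 - not an average of leaf
#' probabilities - so every risk is a multiple of 1/ntree.
#'
#' @param model A model with per-tree votes (a `forest_model`, or any
#'   object with a `predict_risk` method such as an analytic stub).
#' @param x Feature matrix with columns matching the model's feature ids.
#' @param ... Passed to methods.
#' @return Numeric vector of risks in `[0, 1]`.
#' @export
predict_risk <- function(model, x, ...) UseMethod("predict_risk")

#' @rdname predict_risk
#' @export
predict_risk.forest_model <- function(model, x, ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || !identical(colnames(x), model$feature_ids))
    stop("schema error: feature columns do not match model$feature_ids")
  rowMeans(tree_votes(model, x))
}

# Per-tree 0/1 class votes (n x ntree matrix).
tree_votes <- function(model, x) {
  ind <- stats::predict(model$rf, x, predict.all = TRUE)$individual
  matrix(as.integer(ind == "1"), nrow = nrow(x))
}

#' Analytic stub model
#'
#' Wraps a deterministic risk function `f(x) -> [0,1]` as a model usable by
#' the effect-curve routines; used to validate PDP/ALE against closed
#' forms.
#'
#' @param f Function taking a feature matrix, returning a risk vector.
#' @param feature_ids Column names the stub expects.
#' @return Object of class `stub_model`.
#' @export
stub_model <- function(f, feature_ids) {
  structure(list(f = f, feature_ids = feature_ids), class = "stub_model")
}

#' @rdname predict_risk
#' @export
predict_risk.stub_model <- function(model, x, ...) {
  x <- as.matrix(x)
  p <- model$f(x)
  stopifnot(length(p) == nrow(x))
  as.numeric(p)
}

#' Grid search with stratified k-fold cross-validation
#'
#' For every hyperparameter combination, the mean out-of-fold AUC over the
#' same stratified fold assignment is computed; the combination with the
#' highest CV AUC wins. Ties are broken by a grid-order-independent key:
#' smallest ntree, then largest nodesize, then smallest maxnodes, then
#' smallest mtry (the cheapest, most regularized model).
#'
#' @param x,labels Training features and 0/1 labels.
#' @param grid List of [rf_params()]; see [default_tuning_grid()].
#' @param folds Number of CV folds (>= 2).
#' @param seed Integer seed (controls fold assignment and per-fit seeds).
#' @return Object of class `tuning_result` with the full CV table and
#'   `best`.
#' @export
tune_forest <- function(x, labels, grid, folds, seed) {
  stopifnot(length(grid) >= 1L, folds >= 2L)
  x <- as.matrix(x)
  fold <- stratified_folds(labels, folds, substream_seed(seed, "cv_folds"))
  cv_auc <- vapply(grid, function(par) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_forest(x[tr, , drop = FALSE], labels[tr], par,
                      seed = param_seed(seed, par, f))
      roc_auc(predict_risk(m, x[!tr, , drop = FALSE]), labels[!tr])
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  key <- order(-cv_auc,
               vapply(grid, `[[`, numeric(1), "ntree"),
               -vapply(grid, `[[`, numeric(1), "nodesize"),
               vapply(grid, `[[`, numeric(1), "maxnodes"),
               vapply(grid, `[[`, numeric(1), "mtry"))
  best <- grid[[key[1L]]]
  structure(list(grid = grid, cv_auc = cv_auc, best = best,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "tuning_result")
}

# Deterministic per-fit seed, independent of grid order.
param_seed <- function(seed, par, fold) {
  mx <- if (is.infinite(par$maxnodes)) 0 else par$maxnodes
  substream_seed(seed, paste("fit", par$mtry, par$ntree, par$nodesize,
                             mx, fold))
}

#' @export
as.data.frame.tuning_result <- function(x, ...) {
  df <- data.frame(
    mtry = vapply(x$grid, `[[`, integer(1), "mtry"),
    ntree = vapply(x$grid, `[[`, integer(1), "ntree"),
    nodesize = vapply(x$grid, `[[`, integer(1), "nodesize"),
    maxnodes = vapply(x$grid, `[[`, numeric(1), "maxnodes"),
    cv_auc = x$cv_auc)
  df$best <- seq_len(nrow(df)) ==
    which(vapply(x$grid, identical, logical(1), x$best))[1L]
  df
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("Grid search over", length(x$grid), "combinations,", x$folds,
      "-fold CV; best CV AUC", round(max(x$cv_auc), 4), "at mtry =",
      x$best$mtry, ", ntree =", x$best$ntree, ", nodesize =",
      x$best$nodesize, ", maxnodes =", x$best$maxnodes, "\n")
  invisible(x)
}
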