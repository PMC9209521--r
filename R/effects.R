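#' Partial dependence curve
#'
#' For each grid value g in the clip window (default 5th-95th percentile of
#' the observed feature), every subject's feature is forcibly set to g while
#' all other features keep their original values, and the mean predicted
#' risk is recorded. Features with <= 10 unique observed values (indicators,
#' occupancy proportions over few rounds) use their exact observed levels as
#' the grid instead of an equally spaced one.
#'
#' @param model Any model with a [predict_risk()] method.
#' @param x Feature matrix (typically the training data).
#' @param feature_id Column to vary.
#' @param grid_size Number of equally spaced grid points (continuous
#'   features; default 50).
#' @param clip Percentile window `(low, high)` for the grid (default
#'   `c(0.05, 0.95)`).
#' @param reference_level Optional reference value stored on the curve
#'   (conventionally the outcome prevalence, drawn as the reference line).
#' @return Object of class `effect_curve` (kind `"PDP"`).
#' @export
pdp <- function(model, x, feature_id, grid_size = 50L, clip = c(0.05, 0.95),
                reference_level = NA_real_) {
  x <- as.matrix(x)
  if (!feature_id %in% colnames(x))
    stop("schema error: feature '", feature_id, "' not in x")
  v <- x[, feature_id]
  uv <- sort(unique(v))
  if (length(uv) == 1L) {
    warning("degenerate-input: feature '", feature_id,
            "' has zero variance; single-point curve")
    grid <- uv
  } else if (length(uv) <= 10L) {
    grid <- uv  # support-respecting grid for indicators / few-level features
  } else {
    qs <- stats::quantile(v, probs = clip, names = FALSE, type = 7)
    grid <- seq(qs[1], qs[2], length.out = grid_size)
  }
  effect <- vapply(grid, function(g) {
    xi <- x
    xi[, feature_id] <- g
    mean(predict_risk(model, xi))
  }, numeric(1))
  structure(list(feature_id = feature_id, kind = "PDP", grid = grid,
                 effect = effect, clip = clip, n_bins = NA_integer_,
                 n_in_bin = rep(NA_integer_, length(grid)),
                 reference_level = reference_level),
            class = "effect_curve")
}

#' Accumulated local effects curve
#'
#' The clip window of the feature is divided into empirical quantile bins;
#' within each bin the local effect is the mean, over the subjects whose
#' observed value falls in the bin, of the prediction at the bin's upper
#' edge minus the prediction at its lower edge (other features at the
#' subjects' own values - no extrapolation outside locally observed
#' combinations). Local effects are accumulated across bins and centered so
#' the data-weighted mean of the curve is zero. Duplicate quantile edges
#' (heavy ties) are merged. Indicator features fall back to a centered
#' two-level difference.
#'
#' @inheritParams pdp
#' @param n_bins Number of quantile bins (default 20).
#' @return Object of class `effect_curve` (kind `"ALE"`), defined at the
#'   bin edges.
#' @export
ale <- function(model, x, feature_id, n_bins = 20L, clip = c(0.05, 0.95),
                reference_level = NA_real_) {
  x <- as.matrix(x)
  if (!feature_id %in% colnames(x))
    stop("schema error: feature '", feature_id, "' not in x")
  v <- x[, feature_id]
  uv <- sort(unique(v))
  if (length(uv) <= 2L) {
    if (length(uv) == 1L) {
      warning("degenerate-input: zero-variance feature; zero curve")
      return(structure(list(feature_id = feature_id, kind = "ALE",
                            grid = uv, effect = 0, clip = clip,
                            n_bins = 1L, n_in_bin = length(v),
                            reference_level = reference_level),
                       class = "effect_curve"))
    }
    # two-level difference, centered by the level frequencies
    x1 <- x; x1[, feature_id] <- uv[2]
    x0 <- x; x0[, feature_id] <- uv[1]
    d <- mean(predict_risk(model, x1) - predict_risk(model, x0))
    w <- mean(v == uv[2])
    eff <- c(0, d) - (1 - w) * 0 - w * d
    return(structure(list(feature_id = feature_id, kind = "ALE",
                          grid = uv, effect = eff, clip = clip,
                          n_bins = 1L,
                          n_in_bin = c(sum(v == uv[1]), sum(v == uv[2])),
                          reference_level = reference_level),
                     class = "effect_curve"))
  }
  probs <- seq(clip[1], clip[2], length.out = n_bins + 1L)
  edges <- stats::quantile(v, probs = probs, names = FALSE, type = 7)
  if (anyDuplicated(edges)) {
    message("merging ", sum(duplicated(edges)), " tied quantile edge(s) for '",
            feature_id, "'")
    edges <- unique(edges)
  }
  k <- length(edges) - 1L
  inside <- v >= edges[1] & v <= edges[k + 1L]
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), k)
  bin[!inside] <- NA_integer_
  # two batched predictions: every subject at its bin's lower / upper edge
  xi <- x[inside, , drop = FALSE]
  b <- bin[inside]
  xlo <- xi; xlo[, feature_id] <- edges[b]
  xhi <- xi; xhi[, feature_id] <- edges[b + 1L]
  d <- predict_risk(model, xhi) - predict_risk(model, xlo)
  n_in_bin <- as.integer(tabulate(b, nbins = k))
  local <- rep(0, k)
  occupied <- n_in_bin > 0L
  if (any(occupied)) {
    ds <- rowsum(d, b)
    local[as.integer(rownames(ds))] <- ds[, 1L] / n_in_bin[occupied]
  }
  acc <- c(0, cumsum(local))            # accumulated effect at each edge
  center <- sum(n_in_bin * (acc[-1L] + acc[-(k + 1L)]) / 2) / sum(n_in_bin)
  structure(list(feature_id = feature_id, kind = "ALE", grid = edges,
                 effect = acc - center, clip = clip, n_bins = k,
                 n_in_bin = c(n_in_bin, NA_integer_),
                 reference_level = reference_level),
            class = "effect_curve")
}

#' Slope-sign concordance between a PDP and an ALE curve
#'
#' Interpolates the ALE curve onto the PDP grid and compares, per adjacent
#' grid segment of the overlapping range, the sign of the PDP slope with
#' the sign of the ALE slope.
#'
#' @param pdp_curve,ale_curve `effect_curve` objects for the same feature.
#' @return List with `agreement` (fraction of concordant segments) and
#'   `discordant` (data frame of disagreeing segments).
#' @export
curve_concordance <- function(pdp_curve, ale_curve) {
  stopifnot(identical(pdp_curve$feature_id, ale_curve$feature_id))
  lo <- max(min(pdp_curve$grid), min(ale_curve$grid))
  hi <- min(max(pdp_curve$grid), max(ale_curve$grid))
  g <- pdp_curve$grid[pdp_curve$grid >= lo & pdp_curve$grid <= hi]
  if (hi <= lo || length(g) < 2L)
    stop("contract error: curves have no overlapping grid range")
  p <- stats::approx(pdp_curve$grid, pdp_curve$effect, xout = g)$y
  a <- stats::approx(ale_curve$grid, ale_curve$effect, xout = g)$y
  sp <- sign(diff(p)); sa <- sign(diff(a))
  agree <- sp == sa
  list(agreement = mean(agree),
       discordant = data.frame(from = g[-length(g)][!agree],
                               to = g[-1L][!agree],
                               pdp_slope_sign = sp[!agree],
                               ale_slope_sign = sa[!agree]))
}

#' @export
as.data.frame.effect_curve <- function(x, ...) {
  data.frame(feature_id = x$feature_id, kind = x$kind,
             grid_value = x$grid, effect = x$effect,
             n_in_bin = if (length(x$n_in_bin) == length(x$grid))
               x$n_in_bin else NA_integer_,
             row.names = NULL)
}

#' @export
print.effect_curve <- function(x, ...) {
  cat(x$kind, "curve for", x$feature_id, "over", length(x$grid),
      "grid points in [", signif(min(x$grid), 4), ",",
      signif(max(x$grid), 4), "]\n")
  invisible(x)
}

#' Plot an effect curve
#'
#' Base-graphics rendering with the stored reference level as a dotted
#' line (for PDPs, conventionally the outcome prevalence).
#'
#' @param x An `effect_curve`.
#' @param ... Passed to [plot()].
#' @export
plot.effect_curve <- function(x, ...) {
  graphics::plot(x$grid, x$effect, type = "l", xlab = x$feature_id,
                 ylab = if (x$kind == "PDP") "mean predicted risk"
                        else "accumulated local effect",
                 main = paste(x$kind, "-", x$feature_id), ...)
  if (!is.na(x$reference_level))
    graphics::abline(h = x$reference_level, lty = 3, col = "gray40")
  invisible(x)
}
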