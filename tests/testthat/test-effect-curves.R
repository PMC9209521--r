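make_x <- function(n, seed = 1) {
  set.seed(seed)
  cbind(x1 = runif(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.4))
}

test_that("constant models give flat PDP and identically-zero ALE", {
  x <- make_x(300)
  m <- stub_model(function(z) rep(0.3, nrow(z)), colnames(x))
  pc <- pdp(m, x, "x1", grid_size = 20)
  expect_true(all(pc$effect == 0.3))
  ac <- ale(m, x, "x1", n_bins = 10)
  expect_true(all(abs(ac$effect) < 1e-15))
})

test_that("PDP matches the closed-form average for an exact-function model", {
  x <- make_x(2000, seed = 2)
  m <- stub_model(function(z) plogis(3 * z[, "x1"]), colnames(x))
  pc <- pdp(m, x, "x1", grid_size = 40)
  # risk depends on x1 alone, so the PDP is the function itself
  expect_lt(max(abs(pc$effect - plogis(3 * pc$grid))), 1e-9)
  expect_true(all(diff(pc$effect) > 0))
  # grid respects the percentile clip
  qs <- quantile(x[, "x1"], c(0.05, 0.95), names = FALSE)
  expect_gte(min(pc$grid), qs[1]); expect_lte(max(pc$grid), qs[2])
  # mixed model: PDP at g equals the data average with x1 forced to g
  m2 <- stub_model(function(z) plogis(2 * z[, "x1"] - 0.5 * z[, "x2"]),
                   colnames(x))
  pc2 <- pdp(m2, x, "x1", grid_size = 11)
  g <- pc2$grid[5]
  expect_equal(pc2$effect[5], mean(plogis(2 * g - 0.5 * x[, "x2"])),
               tolerance = 1e-12)
})

test_that("PDP handles indicators and degenerate features", {
  x <- make_x(500, seed = 3)
  m <- stub_model(function(z) 0.2 + 0.4 * z[, "x3"], colnames(x))
  pc <- pdp(m, x, "x3", grid_size = 50)
  expect_identical(pc$grid, c(0, 1))  # support-respecting two-point grid
  expect_equal(pc$effect, c(0.2, 0.6), tolerance = 1e-12)
  x0 <- x; x0[, "x2"] <- 5
  expect_warning(p0 <- pdp(m, x0, "x2"), "degenerate")
  expect_length(p0$grid, 1)
  # subject order never matters
  perm <- sample(nrow(x))
  pc_perm <- pdp(m, x[perm, ], "x3", grid_size = 50)
  expect_equal(pc$effect, pc_perm$effect, tolerance = 1e-15)
})

test_that("ALE recovers a linear effect and is centered to machine precision", {
  x <- make_x(2000, seed = 4)
  m <- stub_model(function(z) 0.1 + 0.3 * z[, "x1"] +
                    0.05 * sin(z[, "x2"]), colnames(x))
  ac <- ale(m, x, "x1", n_bins = 20)
  # analytic centered effect: 0.3 * (x - weighted mean over binned data)
  w <- ac$n_in_bin[seq_len(ac$n_bins)]
  mids <- (ac$grid[-1] + ac$grid[-length(ac$grid)]) / 2
  center <- sum(w * mids) / sum(w)
  expect_lt(max(abs(ac$effect - 0.3 * (ac$grid - center))), 0.02)
  # data-weighted mean of the curve is zero
  acc_mid <- (ac$effect[-1] + ac$effect[-length(ac$effect)]) / 2
  expect_lt(abs(sum(w * acc_mid) / sum(w)), 1e-12)
  # a feature the model ignores has a null ALE
  an <- ale(m, x, "x3", n_bins = 10)
  expect_lt(max(abs(an$effect)), 0.01)
})

test_that("PDP and ALE slopes agree in sign for additive models", {
  x <- make_x(1500, seed = 5)
  m <- stub_model(function(z) plogis(1.5 * z[, "x1"] + 0.8 * z[, "x2"]),
                  colnames(x))
  cc <- curve_concordance(pdp(m, x, "x1", grid_size = 30),
                          ale(m, x, "x1", n_bins = 20))
  expect_gte(cc$agreement, 0.95)
  # synthetic monotone curves: identical -> 1, opposed -> 0
  up <- structure(list(feature_id = "f", kind = "PDP", grid = 1:10,
                       effect = (1:10) / 10), class = "effect_curve")
  down <- structure(list(feature_id = "f", kind = "ALE", grid = 1:10,
                         effect = -(1:10) / 10), class = "effect_curve")
  expect_equal(curve_concordance(up, up)$agreement, 1)
  expect_equal(curve_concordance(up, down)$agreement, 0)
  far <- structure(list(feature_id = "f", kind = "ALE", grid = 101:110,
                        effect = 1:10), class = "effect_curve")
  expect_error(curve_concordance(up, far), "overlap")
})
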