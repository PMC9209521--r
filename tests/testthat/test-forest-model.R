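test_that("stratified split honors class proportions, guards, and the seed", {
  y <- c(rep(1L, 16), rep(0L, 84))
  sp <- stratified_split(y, 0.2, seed = 3)
  expect_length(sp$test, 20)
  expect_equal(sum(y[sp$test]), 3)  # round(16 * 0.2)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(y, 0.2, seed = 3))
  expect_false(identical(sp$test, stratified_split(y, 0.2, seed = 4)$test))
  # extreme fraction still leaves each class represented in training
  sp99 <- stratified_split(y, 0.99, seed = 1)
  expect_gte(sum(y[sp99$train]), 1)
  expect_gte(sum(1 - y[sp99$train]), 1)
  expect_error(stratified_split(c(1L, rep(0L, 9)), 0.2, 1), "stratification")
})

test_that("forest fitting is deterministic and honors its contracts", {
  xy <- small_xy(n = 150, k = 4, betas = c(1.5), seed = 6)
  par <- rf_params(3, ntree = 30, nodesize = 5)
  m1 <- fit_forest(xy$x, xy$y, par, seed = 7)
  m2 <- fit_forest(xy$x, xy$y, par, seed = 7)
  expect_identical(m1$oob, m2$oob)
  expect_identical(predict_risk(m1, xy$x), predict_risk(m2, xy$x))
  expect_error(fit_forest(xy$x, xy$y, rf_params(99, ntree = 5), 1),
               "parameter error")
  # vote-fraction support: single tree votes in {0, 1}
  expect_warning(m_one <- fit_forest(xy$x, xy$y, rf_params(3, ntree = 1), seed = 2),
                 "OOB coverage")
  expect_true(all(predict_risk(m_one, xy$x) %in% c(0, 1)))
  # risks are multiples of 1/ntree
  m8 <- suppressWarnings(fit_forest(xy$x, xy$y, rf_params(3, ntree = 8, nodesize = 10), 3))
  r <- predict_risk(m8, xy$x)
  expect_true(all(abs(r * 8 - round(r * 8)) < 1e-12))
  expect_error(predict_risk(m8, xy$x[, rev(colnames(xy$x))]), "schema")
})

test_that("a separating feature drives training vote fractions toward its class", {
  set.seed(11)
  n <- 200
  x <- cbind(sep = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
             noise = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  m <- fit_forest(x, y, rf_params(1, ntree = 100, nodesize = 5), 4)
  expect_gte(min(predict_risk(m, x)[y == 1]), 0.9)
  expect_lte(max(predict_risk(m, x)[y == 0]), 0.1)
})

test_that("grid search selects by CV AUC with a grid-order-independent tie-break", {
  xy <- small_xy(n = 200, k = 4, betas = c(1.5), seed = 12)
  solo <- rf_params(2, ntree = 25, nodesize = 5)
  t1 <- tune_forest(xy$x, xy$y, list(solo), folds = 3, seed = 5)
  expect_identical(t1$best, solo)
  grid <- list(rf_params(2, ntree = 25, nodesize = 5),
               rf_params(4, ntree = 50, nodesize = 1),
               rf_params(2, ntree = 25, nodesize = 10))
  fw <- tune_forest(xy$x, xy$y, grid, folds = 3, seed = 5)
  bw <- tune_forest(xy$x, xy$y, rev(grid), folds = 3, seed = 5)
  expect_identical(fw$best, bw$best)
  expect_identical(sort(fw$cv_auc), sort(bw$cv_auc))
  # exact ties break toward smallest ntree then largest nodesize
  tr <- structure(list(grid = list(rf_params(3, 100, 1), rf_params(3, 50, 1),
                                   rf_params(3, 50, 10)),
                       cv_auc = c(0.7, 0.7, 0.7), folds = 3L, seed = 1L),
                  class = "tuning_result")
  key <- order(-tr$cv_auc,
               vapply(tr$grid, `[[`, numeric(1), "ntree"),
               -vapply(tr$grid, `[[`, numeric(1), "nodesize"))
  expect_identical(tr$grid[[key[1]]], rf_params(3, 50, 10))
})

test_that("a real forest beats a stump-like model on strongly separable data", {
  wins <- 0L
  for (s in 1:3) {
    xy <- small_xy(n = 250, k = 4, betas = c(2.5, 2), seed = 100 + s)
    grid <- list(rf_params(1, ntree = 1, nodesize = nrow(xy$x)),
                 rf_params(3, ntree = 150, nodesize = 5))
    tn <- suppressWarnings(tune_forest(xy$x, xy$y, grid, folds = 3, seed = s))
    wins <- wins + (tn$best$ntree == 150L)
  }
  expect_gte(wins, 2L)
})
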