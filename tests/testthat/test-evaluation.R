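test_that("AUC follows the Mann-Whitney definition with ties counted 1/2", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "undefined")
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
    # complement identity (tie-free scores) and monotone-transform invariance
    s2 <- runif(n)
    expect_equal(roc_auc(s2, y) + roc_auc(s2, 1 - y), 1)
    expect_equal(roc_auc(qlogis(s2), y), roc_auc(s2, y))
  }
})

test_that("the DeLong interval matches pROC and narrows with n", {
  skip_if_not_installed("pROC")
  set.seed(32)
  widths <- c()
  for (n in c(300, 1200)) {
    y <- rbinom(n, 1, 0.3)
    s <- runif(n) + 0.4 * y
    ci <- auc_ci(s, y)
    pr <- as.numeric(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE),
                                  method = "delong"))
    expect_equal(unname(ci), pr[c(1, 3)], tolerance = 1e-10)
    widths <- c(widths, ci[2] - ci[1])
  }
  expect_lt(widths[2], widths[1])
  # perfect separation truncates at 1
  yb <- rep(c(0, 1), each = 10)
  expect_equal(unname(auc_ci(yb, yb)[2]), 1)
})

test_that("the optimal threshold maximizes sens+spec with the low-threshold tie-break", {
  s <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  opt <- optimal_threshold(s, y)
  expect_gt(opt["threshold"], 0.1); expect_lte(opt["threshold"], 0.35)
  expect_equal(unname(opt["sensitivity"]), 1)
  expect_equal(unname(opt["specificity"]), 0.5)
  at5 <- threshold_metrics(s, y, 0.5)
  expect_equal(unname(at5), c(0.5, 1, 0.75))
  perf <- optimal_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(unname(perf[c("sensitivity", "specificity")]), c(1, 1))
  set.seed(33)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    o <- oracle_youden(s, y)
    got <- optimal_threshold(s, y)
    expect_equal(unname(got["sensitivity"] + got["specificity"]), o$sum)
    expect_equal(unname(got["threshold"]), o$threshold)
  }
})

test_that("calibration summaries satisfy their identities and detect miscalibration", {
  set.seed(34)
  s <- runif(200); y <- rbinom(200, 1, 0.3)
  cal <- calibration_in_the_large(s, y)
  expect_equal(unname(cal["difference"]), mean(s) - mean(y))
  expect_equal(unname(calibration_in_the_large(rep(0.3, 10),
                                               rep(c(0, 1), 5))["difference"]),
               -0.2)
  expect_equal(unname(calibration_in_the_large(s, rep(0, 200))["prevalence"]), 0)
  # constant scores collapse to a single merged bin
  cc <- calibration_curve(rep(0.4, 50), rbinom(50, 1, 0.4))
  expect_equal(nrow(cc), 1)
  # well-calibrated simulation stays near the diagonal
  n <- 3000
  s <- runif(n)
  y <- rbinom(n, 1, s)
  cc <- calibration_curve(s, y)
  expect_equal(sum(cc$n), n)
  # ~300 subjects/bin: binomial noise alone reaches ~3 SE = 0.09
  expect_lt(max(abs(cc$mean_predicted - cc$observed_fraction)), 0.1)
  # anti-calibrated scores sit far from the diagonal
  y_anti <- rbinom(n, 1, 1 - s)
  cc_anti <- calibration_curve(s, y_anti)
  expect_gt(max(abs(cc_anti$mean_predicted - cc_anti$observed_fraction)), 0.5)
})

test_that("domain ablation emits one row per model and no-op ablations equal the total", {
  xy <- small_xy(n = 240, k = 4, betas = c(1.5, 1.2), seed = 35)
  config <- run_config(tuning_grid = list(rf_params(2, ntree = 40, nodesize = 5)),
                       cv_folds = 3, seed = 8)
  tab <- xy$table
  abl <- domain_ablation(tab, xy$y, config)
  expect_equal(nrow(abl), 5)  # total + the four exposome domains
  expect_equal(abl$model[1], "total")
  expect_true(all(abl$auc >= 0 & abl$auc <= 1))
  # a domain with zero features leaves the model untouched
  tab2 <- tab
  tab2$features$domain[tab2$features$domain == "demographic"] <- "biological"
  abl2 <- domain_ablation(tab2, xy$y, config)
  noop <- abl2[abl2$model == "without_demographic",
               setdiff(names(abl2), c("model"))]
  total <- abl2[abl2$model == "total", setdiff(names(abl2), c("model"))]
  expect_equal(unname(unlist(noop)), unname(unlist(total)))
  # ablating the only populated domain is an error
  tab3 <- tab
  tab3$features$domain[] <- "biological"
  expect_error(domain_ablation(tab3, xy$y, config), "empty-model")
})

test_that("removing the signal-bearing domain costs discrimination", {
  xy <- small_xy(n = 500, k = 6, betas = c(2, 1.8, 1.6), seed = 36)
  tab <- xy$table
  # concentrate every planted feature in one domain
  planted_exp <- c("e01", "e02", "e03")
  tab$features$domain <- ifelse(tab$features$exposure_id %in% planted_exp,
                                "biological", "environmental")
  config <- run_config(tuning_grid = list(rf_params(3, ntree = 60, nodesize = 5)),
                       cv_folds = 3, seed = 5)
  abl <- domain_ablation(tab, xy$y, config)
  auc_total <- abl$auc[abl$model == "total"]
  auc_wo <- abl$auc[abl$model == "without_biological"]
  expect_gt(auc_total - auc_wo, 0.05)
})
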