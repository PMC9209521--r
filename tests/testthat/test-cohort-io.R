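test_that("a valid long-format cohort round-trips and reads deterministically", {
  f <- toy_cohort_files()
  ch <- read_cohort(f$cohort, f$outcome, f$schema)
  expect_s3_class(ch, "longitudinal_cohort")
  expect_equal(ch$subjects, c("A", "B"))
  expect_equal(unname(ch$outcome), c(1L, 0L))
  expect_equal(nrow(ch$records), nrow(f$records))
  # reading the same files twice yields identical cohorts
  expect_identical(ch, read_cohort(f$cohort, f$outcome, f$schema))
  # write-read round trip is lossless
  p2 <- file.path(f$dir, "c2.csv"); p3 <- file.path(f$dir, "o2.csv")
  write_cohort(ch, p2, p3)
  ch2 <- read_cohort(p2, p3, f$schema)
  expect_equal(ch2$records$value_num, ch$records$value_num, tolerance = 1e-12)
  expect_identical(ch2$outcome, ch$outcome)
})

test_that("validation rejects each malformed-input case with a named error", {
  f <- toy_cohort_files()
  corrupt <- function(mut) {
    rec <- f$records
    rec <- mut(rec)
    p <- tempfile(fileext = ".csv")
    write.csv(rec, p, row.names = FALSE, quote = FALSE)
    p
  }
  # unknown exposure id
  p <- corrupt(function(r) { r$exposure_id[1] <- "unknown_exp"; r })
  expect_error(read_cohort(p, f$outcome, f$schema), "unknown_exp")
  # non-numeric value for a continuous exposure, error cites the row
  p <- corrupt(function(r) { r$value[2] <- "abc"; r })
  expect_error(read_cohort(p, f$outcome, f$schema), "row 2")
  # category outside the schema
  p <- corrupt(function(r) { r$value[7] <- "cohabiting"; r })
  expect_error(read_cohort(p, f$outcome, f$schema), "categories")
  # duplicate (subject, exposure, round)
  p <- corrupt(function(r) rbind(r, r[1, ]))
  expect_error(read_cohort(p, f$outcome, f$schema), "duplication")
  # round outside rounds_measured
  p <- corrupt(function(r) { r$round[6] <- 2; r })
  expect_error(read_cohort(p, f$outcome, f$schema), "rounds_measured")
  # subject with no outcome
  p <- corrupt(function(r) { r$subject_id[1] <- "C"; r })
  expect_error(read_cohort(p, f$outcome, f$schema), "completeness")
})

test_that("random corruptions are never silently accepted", {
  f <- toy_cohort_files()
  base <- read_cohort(f$cohort, f$outcome, f$schema)
  set.seed(20)
  mutations <- list(
    function(r) { r$exposure_id[sample(nrow(r), 1)] <- "nope"; r },
    function(r) { i <- which(r$exposure_id == "bmi"); r$value[sample(i, 1)] <- "x9y"; r },
    function(r) { i <- which(r$exposure_id == "marital"); r$value[sample(i, 1)] <- "zzz"; r },
    function(r) rbind(r, r[sample(nrow(r), 1), ]),
    function(r) { r$round[sample(which(r$exposure_id == "loneliness"), 1)] <- 4; r })
  for (rep in 1:20) {
    mut <- mutations[[sample(length(mutations), 1)]]
    p <- tempfile(fileext = ".csv")
    write.csv(mut(f$records), p, row.names = FALSE, quote = FALSE)
    expect_error(read_cohort(p, f$outcome, f$schema))
  }
  # empty values are treated as absent, not as corruption
  r <- f$records; r$value[1] <- ""
  p <- tempfile(fileext = ".csv")
  write.csv(r, p, row.names = FALSE, quote = FALSE)
  ch <- read_cohort(p, f$outcome, f$schema)
  expect_equal(nrow(ch$records), nrow(base$records) - 1L)
})

test_that("report bundles are deterministic and list only present tables", {
  xy <- small_xy(n = 120, k = 3, seed = 5)
  m <- fit_forest(xy$x, xy$y, rf_params(2, ntree = 20, nodesize = 5), 1)
  rk <- permutation_importance(m, seed = 2)
  res <- list(ranking = rk,
              q_curve = list(q_values = integer(0)),  # empty: no file
              config = run_config(seed = 9))
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- write_report_bundle(res, d1)
  m2 <- write_report_bundle(res, d2)
  expect_false("q_curve.csv" %in% names(m1$files))
  expect_true("importance_ranking.csv" %in% names(m1$files))
  # byte-identical output across runs of the same results
  expect_identical(m1$files, m2$files)
  # written ranking re-reads in identical order
  rr <- read.csv(file.path(d1, "importance_ranking.csv"))
  expect_identical(rr$feature_id, rk$feature_id)
})
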