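test_that("AUE and TOE match their stated examples and conventions", {
  expect_equal(aue_continuous(1:5, rep(5, 5)), 5)
  expect_equal(aue_continuous(c(1, 3, 5), c(2, 4, 8)), 4.5)  # ((2+4)+(4+8))/4
  expect_equal(aue_continuous(2, 7), 7)  # single observation passes through
  expect_equal(toe_continuous(1:5, rep(3, 5)), 0)
  expect_equal(toe_continuous(1:5, 1:5), 1)
  expect_equal(toe_continuous(c(1, 3, 5), c(2, 4, 8)), 1.5)  # mean(1, 2)
  expect_equal(toe_continuous(2, 7), 0)
  expect_error(aue_continuous(integer(0), numeric(0)), "empty")
  expect_error(toe_continuous(c(1, 1), c(2, 3)), "strictly increasing")
})

test_that("categorical occupancy and transition indicators behave as defined", {
  expect_equal(aue_categorical(1:4, c("A", "A", "B", "A"), "A"), 0.75)
  expect_equal(aue_categorical(1:4, c("A", "A", "B", "A"), "C"), 0)
  expect_equal(aue_categorical(c(1, 3), c("A", "B"), "A"), 0.5)  # round 2 missing
  expect_error(aue_categorical(1:2, c("A", "B"), "Z", categories = c("A", "B")),
               "schema")
  ref <- "married"; tgt <- c("widowed", "divorced")
  expect_equal(toe_categorical(1:3, c("married", "married", "divorced"), ref, tgt), 1L)
  expect_equal(toe_categorical(1:2, c("married", "married"), ref, tgt), 0L)
  expect_equal(toe_categorical(1:2, c("divorced", "married"), ref, tgt), 0L)  # wrong direction
  expect_equal(toe_categorical(c(1, 4), c("married", "widowed"), ref, tgt), 1L)  # gaps fine
  expect_error(toe_categorical(1:2, c("a", "b"), "a", c("a", "b")), "overlap")
})

test_that("AUE/TOE agree with dense-integration and pairwise-slope oracles", {
  set.seed(1)
  for (i in 1:200) {
    tr <- random_trajectory()
    a <- aue_continuous(tr$rounds, tr$values)
    o <- oracle_aue_dense(tr$rounds, tr$values)
    expect_lt(abs(a - o), 1e-7 * max(1, abs(o)))
    expect_identical(toe_continuous(tr$rounds, tr$values),
                     oracle_toe(tr$rounds, tr$values))
    # categorical transitions vs all-pairs enumeration
    lab <- sample(c("x", "y", "z"), length(tr$rounds), replace = TRUE)
    expect_identical(toe_categorical(tr$rounds, lab, "x", "y"),
                     oracle_transition(lab, "x", "y"))
  }
})

test_that("summaries are shift/scale equivariant and exact on linear trajectories", {
  set.seed(2)
  for (i in 1:50) {
    tr <- random_trajectory()
    a <- runif(1, -3, 3); b <- runif(1, -10, 10)
    expect_equal(aue_continuous(tr$rounds, a * tr$values + b),
                 a * aue_continuous(tr$rounds, tr$values) + b)
    expect_equal(toe_continuous(tr$rounds, a * tr$values + b),
                 a * toe_continuous(tr$rounds, tr$values))
    # closed form for v(r) = a + b r observed at >= 2 rounds
    if (length(tr$rounds) >= 2) {
      v <- a + b * tr$rounds
      expect_equal(aue_continuous(tr$rounds, v),
                   a + b * (tr$rounds[1] + tr$rounds[length(tr$rounds)]) / 2)
      expect_equal(toe_continuous(tr$rounds, v), b)
    }
  }
})

test_that("occupancy proportions over a state partition sum to one", {
  set.seed(3)
  states <- c("p", "q", "r")
  for (i in 1:20) {
    k <- sample(1:5, 1)
    lab <- sample(states, k, replace = TRUE)
    tot <- sum(vapply(states, function(s)
      aue_categorical(seq_len(k), lab, s), numeric(1)))
    expect_equal(tot, 1)
  }
})

test_that("summarize_cohort builds the expected features and imputes gaps", {
  f <- toy_cohort_files()
  ch <- read_cohort(f$cohort, f$outcome, f$schema)
  tab <- summarize_cohort(ch)
  # 1 multi-round continuous -> AUE+TOE; 1 single-round -> raw;
  # 1 multi-round categorical -> occupancy + transition
  expect_setequal(tab$features$feature_id,
                  c("bmi.AUE", "bmi.TOE", "loneliness.r5",
                    "marital.AUE.married",
                    "marital.TOE.married_to_widowed_divorced"))
  expect_equal(tab$x["A", "bmi.AUE"], aue_continuous(1:5, c(24, 24.5, 25, 25.2, 26)))
  expect_equal(tab$x["A", "bmi.TOE"], toe_continuous(1:5, c(24, 24.5, 25, 25.2, 26)))
  expect_equal(tab$x["A", "marital.AUE.married"], 2 / 3)
  expect_equal(tab$x["A", "marital.TOE.married_to_widowed_divorced"], 1)
  expect_equal(tab$x["B", "loneliness.r5"], 7)
  # remove B's marital records entirely -> mask + mode imputation + log line
  rec <- f$records[!(f$records$subject_id == "B" &
                     f$records$exposure_id == "marital"), ]
  p <- tempfile(fileext = ".csv")
  write.csv(rec, p, row.names = FALSE, quote = FALSE)
  ch2 <- read_cohort(p, f$outcome, f$schema)
  msgs <- capture_messages(tab2 <- summarize_cohort(ch2, verbose = TRUE))
  expect_true(any(grepl("imputed", msgs)))
  expect_true(tab2$missing_mask["B", "marital.AUE.married"])
  expect_equal(tab2$x["B", "marital.TOE.married_to_widowed_divorced"],
               tab2$x["A", "marital.TOE.married_to_widowed_divorced"])  # mode = A's value
  expect_equal(tab2$features$n_imputed[
    tab2$features$feature_id == "marital.AUE.married"], 1)
})

test_that("record order never changes the summary table", {
  f <- toy_cohort_files()
  set.seed(4)
  rec <- f$records[sample(nrow(f$records)), ]
  p <- tempfile(fileext = ".csv")
  write.csv(rec, p, row.names = FALSE, quote = FALSE)
  t1 <- summarize_cohort(read_cohort(f$cohort, f$outcome, f$schema))
  t2 <- summarize_cohort(read_cohort(p, f$outcome, f$schema))
  expect_identical(t1$x, t2$x)
})

test_that("vectorized cohort summaries equal the per-trajectory functions", {
  xy <- small_xy(n = 60, k = 4, seed = 8, mcar = 0.15)
  gen <- xy$gen
  rec <- gen$cohort$records
  for (sub in sample(gen$cohort$subjects, 15)) {
    for (eid in c("e01", "e03")) {
      ri <- rec[rec$subject_id == sub & rec$exposure_id == eid, ]
      fid_a <- paste0(eid, ".AUE"); fid_t <- paste0(eid, ".TOE")
      if (nrow(ri) == 0) {
        expect_true(xy$table$missing_mask[sub, fid_a])
      } else {
        expect_equal(xy$table$x[sub, fid_a],
                     aue_continuous(ri$round, ri$value_num))
        expect_equal(xy$table$x[sub, fid_t],
                     toe_continuous(ri$round, ri$value_num))
      }
    }
  }
})
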