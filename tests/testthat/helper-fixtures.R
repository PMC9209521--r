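# Small in-code fixtures shared across test files.

toy_schema <- function() {
  as_schema(list(
    schema_entry("bmi", "continuous", 1:5, "biological"),
    schema_entry("loneliness", "continuous", 5, "environmental"),
    schema_entry("marital", "categorical", 1:5, "demographic",
                 categories = c("single", "married", "widowed", "divorced"),
                 aue_states = list("married"),
                 reference_states = "married",
                 target_states = c("widowed", "divorced"))))
}

toy_cohort_files <- function(dir = tempfile("cohort")) {
  dir.create(dir)
  rec <- data.frame(
    subject_id = c(rep("A", 5), "A", rep("A", 3), rep("B", 3), "B", "B"),
    exposure_id = c(rep("bmi", 5), "loneliness", rep("marital", 3),
                    rep("bmi", 3), "loneliness", "marital"),
    round = c(1:5, 5, c(1, 3, 5), c(1, 3, 5), 5, 2),
    value = c(24, 24.5, 25, 25.2, 26, 3,
              "married", "married", "divorced",
              22, 22.4, 23, 7, "single"))
  cohort_path <- file.path(dir, "cohort.csv")
  outcome_path <- file.path(dir, "outcome.csv")
  schema_path <- file.path(dir, "schema.yaml")
  write.csv(rec, cohort_path, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(subject_id = c("A", "B"), label = c(1, 0)),
            outcome_path, row.names = FALSE, quote = FALSE)
  write_schema(toy_schema(), schema_path)
  list(cohort = cohort_path, outcome = outcome_path, schema = schema_path,
       dir = dir, records = rec)
}

# Small synthetic spec: k continuous multi-round exposures (features 2k),
# optional planted linear signals on the first AUEs.
small_spec <- function(n = 400, k = 10, betas = numeric(0), seed = 1,
                       prevalence = 0.16, mcar = 0, dropout = 0) {
  exposures <- lapply(seq_len(k), function(i)
    continuous_exposure(sprintf("e%02d", i),
                        c("demographic", "lifestyle", "environmental",
                          "biological")[(i %% 4) + 1],
                        rounds = 1:5, sd_b = 0.3, sd_e = 0.4))
  signal <- list()
  for (i in seq_along(betas))
    signal[[sprintf("e%02d.AUE", i)]] <- list(shape = "linear",
                                              beta = betas[i])
  synthetic_spec(n, 5, exposures, signal_set = signal,
                 target_prevalence = prevalence,
                 mcar_rate = mcar, dropout_hazard = dropout, seed = seed)
}

# Features + labels straight from a small generated cohort.
small_xy <- function(n = 400, k = 10, betas = numeric(0), seed = 1, ...) {
  gen <- generate_cohort(small_spec(n, k, betas, seed, ...))
  tab <- summarize_cohort(gen$cohort)
  list(x = tab$x, y = as.integer(gen$cohort$outcome[tab$subjects]),
       table = tab, gen = gen)
}
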