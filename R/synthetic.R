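#' Continuous exposure blueprint
#'
#' Trajectories follow a random-intercept / random-slope model with
#' independent within-subject noise: subject i's value in round r is
#' `(a_i + b_i * r) + e_ir`, `a_i ~ N(mu_a, sd_a)`, `b_i ~ N(mu_b, sd_b)`,
#' `e_ir ~ N(0, sd_e)`. Under this model the trajectory's time-average
#' (AUE) and mean slope (TOE) map directly onto `a_i`, `b_i`.
#'
#' @param exposure_id,domain,rounds As in [schema_entry()].
#' @param mu_a,sd_a Population mean/SD of the subject intercept.
#' @param mu_b,sd_b Population mean/SD of the subject slope (per round).
#' @param sd_e Within-subject round-to-round noise SD.
#' @return Exposure blueprint (list).
#' @export
continuous_exposure <- function(exposure_id, domain, rounds = 1:5,
                                mu_a = 0, sd_a = 1, mu_b = 0, sd_b = 0.3,
                                sd_e = 0.5) {
  list(exposure_id = exposure_id, var_type = "continuous", domain = domain,
       rounds = sort(unique(as.integer(rounds))),
       mu_a = mu_a, sd_a = sd_a, mu_b = mu_b, sd_b = sd_b, sd_e = sd_e)
}

#' Categorical exposure blueprint
#'
#' Trajectories are Markov chains over the given states: the first
#' measured round is drawn from `init`, each later measured round from the
#' row-stochastic transition matrix `trans`.
#'
#' @inheritParams continuous_exposure
#' @param states Ordered state labels.
#' @param init Initial state distribution (sums to 1).
#' @param trans Square row-stochastic transition matrix (per round).
#' @param aue_states,reference_states,target_states Feature definitions,
#'   as in [schema_entry()].
#' @return Exposure blueprint (list).
#' @export
categorical_exposure <- function(exposure_id, domain, rounds, states, init,
                                 trans, aue_states = NULL,
                                 reference_states = NULL,
                                 target_states = NULL) {
  trans <- as.matrix(trans)
  stopifnot(length(init) == length(states),
            nrow(trans) == length(states), ncol(trans) == length(states))
  if (any(abs(rowSums(trans) - 1) > 1e-8) || abs(sum(init) - 1) > 1e-8)
    stop("spec error: transition matrix rows and init must sum to 1")
  if (is.null(aue_states)) aue_states <- list(states[1L])
  if (length(rounds) > 1L) {
    if (is.null(reference_states)) reference_states <- states[1L]
    if (is.null(target_states))
      target_states <- setdiff(states, reference_states)[1L]
  }
  list(exposure_id = exposure_id, var_type = "categorical", domain = domain,
       rounds = sort(unique(as.integer(rounds))), states = states,
       init = init, trans = trans, aue_states = aue_states,
       reference_states = reference_states, target_states = target_states)
}

#' Synthetic cohort specification
#'
#' @param n_subjects,n_rounds Cohort size and number of exposure rounds.
#' @param exposures List of blueprints from [continuous_exposure()] /
#'   [categorical_exposure()].
#' @param signal_set Named list mapping feature ids (as produced by
#'   [summarize_cohort()], e.g. `"bmi.AUE"`) to effect definitions
#'   `list(shape, beta)` with shape `"linear"` (`beta * z`), `"u_shape"`
#'   (`beta * (z^2 - 1)`) or `"threshold"` (`beta * (z > cut)`), acting on
#'   the cohort-standardized true feature value, on the log-odds scale.
#' @param baseline_log_odds Intercept of the outcome model; ignored when
#'   `target_prevalence` is given.
#' @param target_prevalence If non-`NULL`, the intercept is calibrated by
#'   root-finding so the mean outcome probability equals this value.
#' @param mcar_rate Per-round probability that an observed measurement is
#'   missing completely at random (recycled to `n_rounds`).
#' @param dropout_hazard Per-round hazard of monotone dropout (once out,
#'   always out; outcome labels are never removed).
#' @param outcome_linked_dropout Additive log-odds shift of the dropout
#'   hazard for subjects with the outcome (default 0 = uninformative).
#' @param seed Master seed; all stages draw named substreams from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects, n_rounds, exposures,
                           signal_set = list(),
                           baseline_log_odds = stats::qlogis(0.16),
                           target_prevalence = NULL,
                           mcar_rate = 0, dropout_hazard = 0,
                           outcome_linked_dropout = 0, seed = 1L) {
  mcar_rate <- rep_len(mcar_rate, n_rounds)
  dropout_hazard <- rep_len(dropout_hazard, n_rounds)
  for (e in exposures)
    if (any(e$rounds > n_rounds))
      stop("spec error: exposure '", e$exposure_id,
           "' measured beyond n_rounds")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_rounds = as.integer(n_rounds), exposures = exposures,
                 signal_set = signal_set,
                 baseline_log_odds = baseline_log_odds,
                 target_prevalence = target_prevalence,
                 mcar_rate = mcar_rate, dropout_hazard = dropout_hazard,
                 outcome_linked_dropout = outcome_linked_dropout,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Schema implied by a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return An `exposure_schema` matching the generated cohort.
#' @export
schema_from_spec <- function(spec) {
  as_schema(lapply(spec$exposures, function(e) {
    if (e$var_type == "continuous")
      schema_entry(e$exposure_id, "continuous", e$rounds, e$domain)
    else
      schema_entry(e$exposure_id, "categorical", e$rounds, e$domain,
                   categories = e$states, aue_states = e$aue_states,
                   reference_states = e$reference_states,
                   target_states = e$target_states)
  }))
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Per subject, latent trajectories are drawn for every exposure over its
#' measured rounds; the true summary features (AUE/TOE/occupancy/
#' transition/raw) are computed from these complete trajectories; the
#' outcome is Bernoulli with log-odds `baseline + sum of planted effects`;
#' missingness (per-round MCAR plus monotone dropout) is then applied to
#' the exposure records only. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `cohort` (a `longitudinal_cohort`), `ledger` (a
#'   `ground_truth_ledger`: per-subject true feature values, true log-odds
#'   and probabilities, plus the planted signal set) and `schema`.
#' @export
generate_cohort <- function(spec) {
  n <- spec$n_subjects
  subjects <- sprintf("S%05d", seq_len(n))
  schema <- schema_from_spec(spec)
  truth_cols <- list()
  rec_parts <- list()
  for (e in spec$exposures) {
    R <- length(e$rounds)
    set.seed(substream_seed(spec$seed, paste0("exposure_", e$exposure_id)))
    if (e$var_type == "continuous") {
      a <- stats::rnorm(n, e$mu_a, e$sd_a)
      b <- stats::rnorm(n, e$mu_b, e$sd_b)
      V <- outer(a, rep(1, R)) + outer(b, e$rounds) +
           matrix(stats::rnorm(n * R, 0, e$sd_e), n, R)
      if (R == 1L) {
        truth_cols[[paste0(e$exposure_id, ".r", e$rounds)]] <- V[, 1L]
      } else {
        dr <- diff(e$rounds)
        seg <- (V[, -R, drop = FALSE] + V[, -1L, drop = FALSE]) / 2
        area <- seg %*% dr
        truth_cols[[paste0(e$exposure_id, ".AUE")]] <-
          as.numeric(area) / (e$rounds[R] - e$rounds[1L])
        slopes <- sweep(V[, -1L, drop = FALSE] - V[, -R, drop = FALSE],
                        2, dr, "/")
        truth_cols[[paste0(e$exposure_id, ".TOE")]] <- rowMeans(slopes)
      }
      val_chr <- formatC(V, format = "g", digits = 12)
      rec_parts[[e$exposure_id]] <- data.frame(
        subject_id = rep(subjects, R),
        exposure_id = e$exposure_id,
        round = rep(e$rounds, each = n),
        value = as.vector(val_chr),
        stringsAsFactors = FALSE)
    } else {
      S <- matrix(NA_integer_, n, R)
      S[, 1L] <- sample.int(length(e$states), n, replace = TRUE,
                            prob = e$init)
      cum <- t(apply(e$trans, 1, cumsum))
      if (R > 1L) for (r in 2:R) {
        u <- stats::runif(n)
        S[, r] <- max.col(cum[S[, r - 1L], , drop = FALSE] >=
                            matrix(u, n, length(e$states)),
                          ties.method = "first")
      }
      lab <- matrix(e$states[S], n, R)
      if (R == 1L) {
        for (st in e$aue_states)
          truth_cols[[paste0(e$exposure_id, ".r", e$rounds, ".",
                             state_tag(st))]] <-
            as.numeric(lab[, 1L] %in% st)
      } else {
        for (st in e$aue_states)
          truth_cols[[paste0(e$exposure_id, ".AUE.", state_tag(st))]] <-
            rowMeans(matrix(lab %in% st, n, R))
        in_ref <- matrix(lab %in% e$reference_states, n, R)
        in_tgt <- matrix(lab %in% e$target_states, n, R)
        seen_ref <- t(apply(in_ref, 1, cumsum)) > 0
        fired <- in_tgt[, -1L, drop = FALSE] &
                 seen_ref[, -R, drop = FALSE]
        truth_cols[[paste0(e$exposure_id, ".TOE.",
                           state_tag(e$reference_states), "_to_",
                           state_tag(e$target_states))]] <-
          as.numeric(rowSums(fired) > 0)
      }
      rec_parts[[e$exposure_id]] <- data.frame(
        subject_id = rep(subjects, R),
        exposure_id = e$exposure_id,
        round = rep(e$rounds, each = n),
        value = as.vector(lab),
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(cbind, truth_cols)
  rownames(truth) <- subjects

  # planted effects on the log-odds scale, on cohort-standardized truths
  eta <- rep(0, n)
  for (fid in names(spec$signal_set)) {
    if (!fid %in% colnames(truth))
      stop("spec error: signal feature '", fid,
           "' not produced by the declared exposures")
    eff <- spec$signal_set[[fid]]
    v <- truth[, fid]
    z <- (v - mean(v)) / stats::sd(v)
    eta <- eta + switch(eff$shape,
      linear = eff$beta * z,
      u_shape = eff$beta * (z^2 - 1),
      threshold = eff$beta * (z > (if (is.null(eff$cut)) 0 else eff$cut)),
      stop("spec error: unknown effect shape '", eff$shape, "'"))
  }
  baseline <- spec$baseline_log_odds
  if (!is.null(spec$target_prevalence)) {
    baseline <- stats::uniroot(function(b)
      mean(stats::plogis(b + eta)) - spec$target_prevalence,
      interval = c(-20, 20), tol = 1e-10)$root
  }
  prob <- stats::plogis(baseline + eta)
  set.seed(substream_seed(spec$seed, "outcome"))
  outcome <- stats::rbinom(n, 1L, prob)
  names(outcome) <- subjects

  rec <- do.call(rbind, rec_parts)
  # monotone dropout: subject leaves at the first round where the hazard
  # fires and never returns; outcome labels are kept for everyone
  set.seed(substream_seed(spec$seed, "dropout"))
  haz <- matrix(rep(spec$dropout_hazard, each = n), n, spec$n_rounds)
  if (spec$outcome_linked_dropout != 0) {
    shift <- spec$outcome_linked_dropout * outcome
    haz <- stats::plogis(stats::qlogis(pmin(pmax(haz, 1e-12), 1 - 1e-12)) +
                         shift) * (haz > 0)
  }
  fires <- matrix(stats::runif(n * spec$n_rounds), n, spec$n_rounds) < haz
  first_out <- apply(fires, 1, function(z)
    if (any(z)) which(z)[1L] else spec$n_rounds + 1L)
  keep_drop <- rec$round < first_out[match(rec$subject_id, subjects)]
  # MCAR per record, rate by round
  set.seed(substream_seed(spec$seed, "mcar"))
  keep_mcar <- stats::runif(nrow(rec)) >= spec$mcar_rate[rec$round]
  rec <- rec[keep_drop & keep_mcar, , drop = FALSE]

  cohort <- validate_records(rec, schema, outcome,
                             outcome_round = spec$n_rounds + 1L)
  ledger <- structure(list(subjects = subjects, truth = truth,
                           true_log_odds = baseline + eta,
                           true_prob = prob,
                           signal_set = spec$signal_set,
                           baseline_log_odds = baseline),
                      class = "ground_truth_ledger")
  list(cohort = cohort, ledger = ledger, schema = schema)
}

#' Default cohort specification emulating the motivating study
#'
#' 3419 subjects, 5 exposure rounds, 51 exposures (45 multi-round + 6
#' single-round) across the four exposome domains yielding exactly 96
#' summary features, 9 planted signal features (a mix of AUE and TOE
#' summaries including one u-shaped effect and one categorical transition
#' indicator), an intercept calibrated to 16% outcome prevalence, and
#' round-wise missingness rising with round.
#'
#' @param seed Master seed.
#' @return A [synthetic_spec()].
#' @export
default_paper_like_spec <- function(seed = 1L) {
  cont <- function(id, dom, rounds = 1:5, mu_a = 0, sd_a = 1, mu_b = 0,
                   sd_b = 0.25, sd_e = 0.5)
    continuous_exposure(id, dom, rounds, mu_a, sd_a, mu_b, sd_b, sd_e)
  yn <- function(id, dom, rounds, p_yes = 0.15, p_on = 0.06, p_off = 0.02)
    categorical_exposure(id, dom, rounds, states = c("no", "yes"),
                         init = c(1 - p_yes, p_yes),
                         trans = matrix(c(1 - p_on, p_on, p_off, 1 - p_off),
                                        2, 2, byrow = TRUE),
                         aue_states = list("yes"),
                         reference_states = "no", target_states = "yes")
  marital <- categorical_exposure(
    "marital", "demographic", 1:5,
    states = c("single", "married", "widowed", "divorced"),
    init = c(0.12, 0.82, 0.02, 0.04),
    trans = matrix(c(0.90, 0.09, 0.00, 0.01,
                     0.00, 0.955, 0.025, 0.02,
                     0.00, 0.02, 0.97, 0.01,
                     0.00, 0.05, 0.00, 0.95), 4, 4, byrow = TRUE),
    aue_states = list("married"),
    reference_states = "married", target_states = c("widowed", "divorced"))
  exposures <- c(
    # demographic: 3 continuous multi, 2 categorical multi, 2 singles
    list(cont("age", "demographic", 1:5, mu_a = 45, sd_a = 8, mu_b = 5,
              sd_b = 0.01, sd_e = 0.1),
         cont("working_hours", "demographic", 2:5, mu_a = 24, sd_a = 14,
              mu_b = -1.2, sd_b = 1.5, sd_e = 4),
         cont("education_years", "demographic", 1:4, mu_a = 12, sd_a = 3,
              mu_b = 0.05, sd_b = 0.05, sd_e = 0.3),
         marital,
         yn("single_household", "demographic", 2:5, 0.18, 0.04, 0.03),
         continuous_exposure("sex_male", "demographic", 1, mu_a = 0.48,
                             sd_a = 0.5, sd_e = 0),
         continuous_exposure("non_dutch", "demographic", 1, mu_a = 0.05,
                             sd_a = 0.22, sd_e = 0)),
    # lifestyle: 7 continuous multi, 4 categorical multi
    list(cont("alcohol_glasses", "lifestyle", 1:5, mu_a = 1.2, sd_a = 1.1,
              mu_b = -0.05, sd_b = 0.1, sd_e = 0.4),
         cont("cigarettes_per_day", "lifestyle", 1:5, mu_a = 4, sd_a = 6,
              mu_b = -0.3, sd_b = 0.4, sd_e = 1),
         cont("pack_years", "lifestyle", 1:5, mu_a = 9, sd_a = 11,
              mu_b = 0.8, sd_b = 0.5, sd_e = 0.8),
         cont("diet_index", "lifestyle", 2:4, mu_a = 70, sd_a = 15,
              mu_b = 0.5, sd_b = 1, sd_e = 4),
         cont("sleep_hours", "lifestyle", 1:5, mu_a = 7.2, sd_a = 0.9,
              mu_b = -0.03, sd_b = 0.06, sd_e = 0.4),
         cont("sedentary_hours", "lifestyle", 2:5, mu_a = 6, sd_a = 2,
              mu_b = 0.2, sd_b = 0.2, sd_e = 0.8),
         cont("fruit_veg_grams", "lifestyle", 2:4, mu_a = 250, sd_a = 90,
              mu_b = 5, sd_b = 8, sd_e = 40),
         yn("current_smoker", "lifestyle", 1:5, 0.3, 0.02, 0.06),
         yn("heavy_drinker", "lifestyle", 1:5, 0.08, 0.02, 0.04),
         yn("active_job", "lifestyle", 1:5, 0.35, 0.05, 0.05),
         yn("meets_activity_norm", "lifestyle", 2:5, 0.55, 0.08, 0.08)),
    # environmental: 10 continuous multi, 3 categorical multi, 2 singles
    list(cont("no2", "environmental", 1:5, mu_a = 28, sd_a = 2, mu_b = -1.6,
              sd_b = 0.15, sd_e = 0.4),
         cont("pm25", "environmental", 1:5, mu_a = 16, sd_a = 1.5,
              mu_b = -0.8, sd_b = 0.1, sd_e = 0.3),
         cont("elemental_carbon", "environmental", 1:5, mu_a = 1.1,
              sd_a = 0.2, mu_b = -0.05, sd_b = 0.02, sd_e = 0.05),
         cont("rail_noise", "environmental", 1:5, mu_a = 48, sd_a = 6,
              mu_b = 0, sd_b = 0.2, sd_e = 1),
         cont("road_noise", "environmental", 1:5, mu_a = 54, sd_a = 5,
              mu_b = 0.1, sd_b = 0.2, sd_e = 1),
         cont("ndvi_300m", "environmental", 1:5, mu_a = 0.45, sd_a = 0.12,
              mu_b = 0.002, sd_b = 0.004, sd_e = 0.02),
         cont("ndvi_1000m", "environmental", 1:5, mu_a = 0.5, sd_a = 0.1,
              mu_b = 0.002, sd_b = 0.004, sd_e = 0.02),
         cont("green_distance", "environmental", 1:5, mu_a = 300, sd_a = 150,
              mu_b = 2, sd_b = 8, sd_e = 30),
         cont("social_support_pos", "environmental", 1:3, mu_a = 24,
              sd_a = 4, mu_b = 0.1, sd_b = 0.3, sd_e = 1.2),
         cont("social_support_neg", "environmental", 1:3, mu_a = 13,
              sd_a = 3, mu_b = 0.1, sd_b = 0.3, sd_e = 1.2),
         yn("damp_stains", "environmental", 2:3, 0.2, 0.08, 0.1),
         yn("mold_growth", "environmental", 2:3, 0.12, 0.05, 0.1),
         yn("pet_in_house", "environmental", 2:3, 0.5, 0.05, 0.05),
         continuous_exposure("social_support_elderly", "environmental", 5,
                             mu_a = 36, sd_a = 6, sd_e = 0),
         continuous_exposure("loneliness", "environmental", 5, mu_a = 2.4,
                             sd_a = 2.4, sd_e = 0)),
    # biological: 13 continuous multi, 3 categorical multi, 2 singles
    list(cont("bmi", "biological", 1:5, mu_a = 24.5, sd_a = 3.2, mu_b = 0.17,
              sd_b = 0.15, sd_e = 0.5),
         cont("waist_hip_ratio", "biological", 2:5, mu_a = 0.87, sd_a = 0.08,
              mu_b = 0.004, sd_b = 0.003, sd_e = 0.01),
         cont("waist_circumference", "biological", 2:5, mu_a = 88, sd_a = 11,
              mu_b = 0.8, sd_b = 0.5, sd_e = 1.5),
         cont("pulse_rate", "biological", 1:5, mu_a = 68, sd_a = 9,
              mu_b = 0.1, sd_b = 0.4, sd_e = 3),
         cont("systolic_bp", "biological", 1:5, mu_a = 122, sd_a = 13,
              mu_b = 1.2, sd_b = 0.8, sd_e = 5),
         cont("diastolic_bp", "biological", 1:5, mu_a = 77, sd_a = 9,
              mu_b = 0.3, sd_b = 0.5, sd_e = 3),
         cont("total_cholesterol", "biological", 1:5, mu_a = 5.3, sd_a = 0.9,
              mu_b = 0.04, sd_b = 0.04, sd_e = 0.25),
         cont("hdl_cholesterol", "biological", 1:5, mu_a = 1.35, sd_a = 0.3,
              mu_b = 0.005, sd_b = 0.01, sd_e = 0.08),
         cont("chol_ratio", "biological", 1:5, mu_a = 4.1, sd_a = 1.1,
              mu_b = 0.02, sd_b = 0.06, sd_e = 0.2),
         cont("triglycerides", "biological", 1:5, mu_a = 1.3, sd_a = 0.6,
              mu_b = 0.02, sd_b = 0.03, sd_e = 0.2),
         cont("ldl_cholesterol", "biological", 1:5, mu_a = 3.2, sd_a = 0.8,
              mu_b = 0.03, sd_b = 0.03, sd_e = 0.2),
         cont("hemoglobin", "biological", 1:5, mu_a = 8.8, sd_a = 0.6,
              mu_b = -0.01, sd_b = 0.02, sd_e = 0.15),
         cont("resting_hrv", "biological", 1:5, mu_a = 42, sd_a = 12,
              mu_b = -0.6, sd_b = 0.4, sd_e = 3),
         yn("bp_medication", "biological", 1:5, 0.06, 0.05, 0.01),
         yn("chol_medication", "biological", 1:5, 0.03, 0.04, 0.01),
         yn("diabetes_medication", "biological", 1:5, 0.02, 0.015, 0.005),
         continuous_exposure("glucose_r5", "biological", 5, mu_a = 5.4,
                             sd_a = 0.8, sd_e = 0),
         continuous_exposure("crp_r5", "biological", 5, mu_a = 2.1,
                             sd_a = 1.8, sd_e = 0)))
  signal_set <- list(
    working_hours.AUE = list(shape = "linear", beta = -0.55),
    waist_circumference.AUE = list(shape = "linear", beta = 0.60),
    bmi.AUE = list(shape = "u_shape", beta = 0.50),
    loneliness.r5 = list(shape = "linear", beta = 0.55),
    waist_hip_ratio.AUE = list(shape = "linear", beta = 0.45),
    age.AUE = list(shape = "linear", beta = 0.60),
    pack_years.AUE = list(shape = "linear", beta = 0.50),
    chol_ratio.TOE = list(shape = "linear", beta = 0.50),
    marital.TOE.married_to_widowed_divorced =
      list(shape = "linear", beta = 0.60))
  synthetic_spec(n_subjects = 3419L, n_rounds = 5L,
                 exposures = exposures, signal_set = signal_set,
                 target_prevalence = 0.16,
                 mcar_rate = c(0.02, 0.05, 0.08, 0.10, 0.12),
                 dropout_hazard = c(0, 0.02, 0.03, 0.04, 0.05),
                 seed = seed)
}

#' Ground-truth recovery report
#'
#' Compares a pipeline run against the generator's ledger: which planted
#' signal features were recovered in the selected top-q set, the rank of
#' every planted feature, the sign agreement between each planted monotone
#' effect and the slope of its PDP, and whether a planted u-shaped effect
#' produces a PDP slope sign change inside the clip window.
#'
#' @param ledger A `ground_truth_ledger` from [generate_cohort()].
#' @param result A `pipeline_result` from [run_pipeline()] (or a list with
#'   `ranking`, `q_curve` and optionally `effect_curves`).
#' @return List with `recovered_fraction`, `planted_ranks`,
#'   `pdp_sign_agreement` and `u_shape_detected`.
#' @export
recovery_report <- function(ledger, result) {
  planted <- names(ledger$signal_set)
  ranking <- result$ranking
  if (!all(planted %in% ranking$feature_id))
    stop("contract error: planted features missing from the ranking")
  q <- result$q_curve$selected_q
  topq <- ranking$feature_id[seq_len(q)]
  ranks <- stats::setNames(match(planted, ranking$feature_id), planted)
  sign_agree <- NULL
  u_detect <- NULL
  curves <- result$effect_curves
  if (!is.null(curves)) {
    pdps <- curves[vapply(curves, function(cv) cv$kind == "PDP", logical(1))]
    names(pdps) <- vapply(pdps, `[[`, character(1), "feature_id")
    for (fid in planted) {
      eff <- ledger$signal_set[[fid]]
      if (!fid %in% names(pdps)) next
      cv <- pdps[[fid]]
      if (length(cv$grid) < 2L) next
      slopes <- diff(cv$effect) / diff(cv$grid)
      if (eff$shape == "linear") {
        # net slope across the window vs the planted direction
        net <- cv$effect[length(cv$effect)] - cv$effect[1L]
        sign_agree[[fid]] <- as.numeric(sign(net) == sign(eff$beta))
      } else if (eff$shape == "u_shape") {
        u_detect[[fid]] <- any(slopes > 0) && any(slopes < 0)
      }
    }
  }
  list(recovered = intersect(planted, topq),
       recovered_fraction = length(intersect(planted, topq)) / length(planted),
       selected_q = q,
       planted_ranks = ranks,
       pdp_sign_agreement = unlist(sign_agree),
       u_shape_detected = unlist(u_detect))
}
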