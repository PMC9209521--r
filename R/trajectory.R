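#' Area-Under-the-Exposure for a continuous trajectory
#'
#' The trajectory is the piecewise-linear interpolant through the observed
#' (round, value) points; the AUE is the trapezoidal area under it between
#' the first and last observed round, divided by their span - i.e. the
#' time-average of the exposure. This makes subjects observed over
#' different numbers of rounds comparable and is well defined under missing
#' rounds (unobserved rounds are simply skipped). A single observation
#' yields that value.
#'
#' @param rounds Strictly increasing integer vector of observed rounds.
#' @param values Parallel numeric vector of exposure values.
#' @return The time-averaged exposure (scalar).
#' @export
aue_continuous <- function(rounds, values) {
  check_trajectory(rounds, values)
  n <- length(rounds)
  if (n == 1L) return(as.numeric(values))
  dr <- diff(rounds)
  area <- sum((values[-n] + values[-1L]) / 2 * dr)
  area / (rounds[n] - rounds[1L])
}

#' Trend-Of-the-Exposure for a continuous trajectory
#'
#' The slope between each pair of consecutive observed rounds is computed
#' and the unweighted mean of these slopes is returned. Positive values
#' indicate an upward trend in exposure over time, negative a downward
#' trend. A single observation yields 0 (no observable trend).
#'
#' @inheritParams aue_continuous
#' @return Mean per-pair slope (scalar).
#' @export
toe_continuous <- function(rounds, values) {
  check_trajectory(rounds, values)
  if (length(rounds) == 1L) return(0)
  mean(diff(values) / diff(rounds))
}

#' Occupancy proportion (categorical AUE)
#'
#' Fraction of observed rounds in which the subject occupied one of the
#' given states. Unobserved rounds are excluded from the denominator, so
#' the proportion is well defined under missing rounds.
#'
#' @param rounds Observed rounds (strictly increasing).
#' @param values Parallel character vector of state labels.
#' @param states Character vector: the state set of interest.
#' @param categories Optional full category set for validation.
#' @return Proportion in `[0, 1]`.
#' @export
aue_categorical <- function(rounds, values, states, categories = NULL) {
  check_trajectory(rounds, values)
  if (!is.null(categories) && !all(states %in% categories))
    stop("schema error: states outside schema categories: ",
         paste(setdiff(states, categories), collapse = ", "))
  mean(values %in% states)
}

#' Transition indicator (categorical TOE)
#'
#' Returns 1 if a reference-state observation is later followed - at any
#' subsequent observed round, not necessarily the next - by a target-state
#' observation ("from married to widowed or divorced"-style transitions),
#' else 0. Direction-sensitive: a target state observed before any
#' reference state does not count.
#'
#' @inheritParams aue_categorical
#' @param reference_states,target_states Disjoint state sets.
#' @return 0 or 1.
#' @export
toe_categorical <- function(rounds, values, reference_states, target_states) {
  check_trajectory(rounds, values)
  if (length(intersect(reference_states, target_states)) > 0L)
    stop("schema error: reference_states and target_states overlap")
  n <- length(values)
  if (n < 2L) return(0L)
  in_ref <- values %in% reference_states
  in_tgt <- values %in% target_states
  seen_ref <- c(FALSE, cumsum(in_ref)[-n] > 0)  # reference strictly earlier
  as.integer(any(in_tgt & seen_ref))
}

check_trajectory <- function(rounds, values) {
  if (length(rounds) == 0L)
    stop("contract violation: empty trajectory")
  if (length(rounds) != length(values))
    stop("contract violation: rounds and values differ in length")
  if (length(rounds) > 1L && any(diff(rounds) <= 0))
    stop("contract violation: rounds must be strictly increasing")
  invisible(TRUE)
}

#' Summarize a cohort into the subject x feature table
#'
#' Implements the trajectory-summarization step: every multi-round
#' continuous exposure yields an AUE and a TOE feature; every multi-round
#' categorical exposure yields one occupancy-proportion (AUE) feature per
#' configured state set and one transition-indicator (TOE) feature per
#' configured reference/target pair; single-round exposures pass through as
#' raw features (latest observed value; categorical singles as occupancy
#' indicators). Subjects with no observation at all for an exposure are
#' flagged in the missing mask and imputed for modelling by the cohort
#' median (continuous/proportions) or mode (indicators); imputation counts
#' are recorded per feature.
#'
#' @param cohort A `longitudinal_cohort` (see [read_cohort()]).
#' @param schema Optional `exposure_schema`; defaults to the one stored in
#'   the cohort.
#' @param verbose Emit a message per imputed feature.
#' @return An object of class `summary_features`: list with `subjects`,
#'   `features` (data.frame: feature_id, exposure_id, kind, domain,
#'   n_imputed), numeric matrix `x` (subjects x features, imputed) and
#'   logical matrix `missing_mask`.
#' @export
summarize_cohort <- function(cohort, schema = cohort$schema, verbose = FALSE) {
  rec <- cohort$records
  unknown <- setdiff(unique(rec$exposure_id), names(schema))
  if (length(unknown) > 0L)
    stop("schema error: exposure(s) missing from schema: ",
         paste(unknown, collapse = ", "))
  subjects <- cohort$subjects
  n <- length(subjects)
  cols <- list()
  feat <- list()
  add <- function(id, eid, kind, domain, v) {
    cols[[id]] <<- v
    feat[[id]] <<- data.frame(feature_id = id, exposure_id = eid,
                              kind = kind, domain = domain,
                              stringsAsFactors = FALSE)
  }
  for (eid in names(schema)) {
    e <- schema[[eid]]
    ri <- rec[rec$exposure_id == eid, , drop = FALSE]  # sorted subject, round
    g <- factor(ri$subject_id, levels = subjects)
    if (e$var_type == "continuous") {
      if (e$single_round) {
        # latest observed value per subject
        v <- rep(NA_real_, n)
        if (nrow(ri) > 0L) {
          last <- !duplicated(g, fromLast = TRUE) & !is.na(g)
          v[as.integer(g[last])] <- ri$value_num[last]
        }
        add(paste0(eid, ".r", e$rounds_measured), eid, "raw_single_round",
            e$domain, v)
      } else {
        s <- grouped_aue_toe(as.integer(g), ri$round, ri$value_num, n)
        add(paste0(eid, ".AUE"), eid, "AUE", e$domain, s$aue)
        add(paste0(eid, ".TOE"), eid, "TOE", e$domain, s$toe)
      }
    } else {
      gi <- as.integer(g)
      if (e$single_round) {
        for (st in e$aue_states) {
          v <- rep(NA_real_, n)
          if (nrow(ri) > 0L) {
            last <- !duplicated(g, fromLast = TRUE) & !is.na(g)
            v[gi[last]] <- as.numeric(ri$value[last] %in% st)
          }
          add(paste0(eid, ".r", e$rounds_measured, ".",
                     state_tag(st)), eid, "raw_single_round", e$domain, v)
        }
      } else {
        for (st in e$aue_states) {
          v <- rep(NA_real_, n)
          if (nrow(ri) > 0L) {
            ok <- !is.na(gi)
            hits <- rowsum(as.numeric(ri$value[ok] %in% st), gi[ok])
            counts <- rowsum(rep(1, sum(ok)), gi[ok])
            v[as.integer(rownames(hits))] <- hits[, 1L] / counts[, 1L]
          }
          add(paste0(eid, ".AUE.", state_tag(st)), eid, "AUE_state",
              e$domain, v)
        }
        v <- rep(NA_real_, n)
        if (nrow(ri) > 0L) {
          tr <- grouped_transition(gi, ri$value, e$reference_states,
                                   e$target_states, n)
          v <- tr
        }
        add(paste0(eid, ".TOE.", state_tag(e$reference_states), "_to_",
                   state_tag(e$target_states)), eid, "TOE_transition",
            e$domain, v)
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- subjects
  features <- do.call(rbind, feat)
  rownames(features) <- NULL
  missing_mask <- is.na(x)
  features$n_imputed <- colSums(missing_mask)
  # impute: median for continuous-valued kinds, mode for indicators
  for (j in seq_len(ncol(x))) {
    mj <- missing_mask[, j]
    if (!any(mj)) next
    obs <- x[!mj, j]
    if (length(obs) == 0L)
      stop("cohort error: feature ", colnames(x)[j], " observed for no subject")
    fill <- if (features$kind[j] %in% c("TOE_transition") ||
                all(obs %in% c(0, 1))) {
      as.numeric(names(which.max(table(obs))))  # mode
    } else stats::median(obs)
    x[mj, j] <- fill
    if (verbose)
      message("imputed ", sum(mj), " subject(s) for feature ",
              colnames(x)[j])
  }
  structure(list(subjects = subjects, features = features, x = x,
                 missing_mask = missing_mask),
            class = "summary_features")
}

state_tag <- function(states) {
  gsub("[^A-Za-z0-9_]+", "_", paste(states, collapse = "_"))
}

# Vectorized per-subject AUE/TOE over grouped long records.
# gi: group index per record (1..n, sorted non-decreasing within exposure);
# records are pre-sorted by subject then round.
grouped_aue_toe <- function(gi, rounds, values, n) {
  aue <- rep(NA_real_, n); toe <- rep(NA_real_, n)
  ok <- !is.na(gi)
  gi <- gi[ok]; rounds <- rounds[ok]; values <- values[ok]
  if (length(gi) == 0L) return(list(aue = aue, toe = toe))
  m <- length(gi)
  same <- if (m > 1L) gi[-1L] == gi[-m] else logical(0)  # consecutive pairs
  first <- !duplicated(gi); last <- !duplicated(gi, fromLast = TRUE)
  # single-observation subjects
  single <- first & last
  aue[gi[single]] <- values[single]
  toe[gi[single]] <- 0
  if (any(same)) {
    i <- which(same)
    dr <- rounds[i + 1L] - rounds[i]
    seg_area <- (values[i] + values[i + 1L]) / 2 * dr
    slopes <- (values[i + 1L] - values[i]) / dr
    gseg <- gi[i]
    area <- rowsum(seg_area, gseg)
    slope_sum <- rowsum(slopes, gseg)
    nseg <- rowsum(rep(1, length(i)), gseg)
    sub <- as.integer(rownames(area))
    span <- rounds[last][match(sub, gi[last])] -
            rounds[first][match(sub, gi[first])]
    aue[sub] <- area[, 1L] / span
    toe[sub] <- slope_sum[, 1L] / nseg[, 1L]
  }
  list(aue = aue, toe = toe)
}

# Vectorized transition indicator per subject over grouped records.
grouped_transition <- function(gi, values, ref, tgt, n) {
  out <- rep(NA_real_, n)
  ok <- !is.na(gi)
  gi <- gi[ok]; values <- values[ok]
  if (length(gi) == 0L) return(out)
  in_ref <- values %in% ref
  in_tgt <- values %in% tgt
  cr <- stats::ave(as.numeric(in_ref), gi, FUN = cumsum)
  first <- !duplicated(gi)
  seen_ref_before <- c(0, cr[-length(cr)])
  seen_ref_before[first] <- 0
  fired <- in_tgt & seen_ref_before > 0
  hit <- rowsum(as.numeric(fired), gi)
  out[as.integer(rownames(hit))] <- as.numeric(hit[, 1L] > 0)
  out
}

#' @export
print.summary_features <- function(x, ...) {
  cat("Summary feature table:", length(x$subjects), "subjects x",
      nrow(x$features), "features (",
      sum(x$features$kind %in% c("AUE", "AUE_state")), "AUE,",
      sum(x$features$kind %in% c("TOE", "TOE_transition")), "TOE,",
      sum(x$features$kind == "raw_single_round"), "raw );",
      sum(x$missing_mask), "imputed entries\n")
  invisible(x)
}

#' @export
as.data.frame.summary_features <- function(x, ...) {
  data.frame(subject_id = x$subjects, x$x, check.names = FALSE,
             row.names = NULL)
}
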