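# Independent oracles, kept deliberately naive.

# Dense numerical integration of the piecewise-linear interpolant.
# The fine grid is laid out segment by segment (so every knot is a grid
# point and the trapezoid rule carries no discretization bias).
oracle_aue_dense <- function(rounds, values, per_segment = 2001L) {
  if (length(rounds) == 1L) return(values)
  area <- 0
  for (i in seq_len(length(rounds) - 1L)) {
    g <- seq(rounds[i], rounds[i + 1L], length.out = per_segment)
    f <- approx(rounds, values, xout = g)$y
    area <- area + sum((f[-1] + f[-per_segment]) / 2 * diff(g))
  }
  area / (rounds[length(rounds)] - rounds[1])
}

# Brute-force mean of consecutive pairwise slopes.
oracle_toe <- function(rounds, values) {
  if (length(rounds) == 1L) return(0)
  s <- numeric(0)
  for (i in seq_len(length(rounds) - 1L))
    s <- c(s, (values[i + 1] - values[i]) / (rounds[i + 1] - rounds[i]))
  mean(s)
}

# Transition indicator by enumeration over all index pairs.
oracle_transition <- function(values, ref, tgt) {
  n <- length(values)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (j > i && values[i] %in% ref && values[j] %in% tgt) return(1L)
  0L
}

# AUC by enumeration over all positive x negative pairs, ties 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Best sens+spec by scanning a dense threshold set (rule: positive iff
# score > t); returns the maximum and the smallest achieving threshold.
oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best_sum <- -Inf; best_t <- NA
  for (t in cand) {
    pred <- scores > t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    if (sens + spec > best_sum + 1e-12) { best_sum <- sens + spec; best_t <- t }
  }
  list(sum = best_sum, threshold = best_t)
}

random_trajectory <- function() {
  k <- sample(1:5, 1)
  rounds <- sort(sample(1:5, k))
  list(rounds = rounds, values = round(rnorm(k, 0, 5), 3))
}
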