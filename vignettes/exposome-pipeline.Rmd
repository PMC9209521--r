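---
title: "Identifying longitudinal exposome predictors with random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying longitudinal exposome predictors with random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Population cohorts increasingly measure a wide *exposome* — demographic,
lifestyle, environmental and biological exposures — repeatedly over decades,
alongside health outcomes. Classical single-exposure regression neither
ranks many candidate predictors jointly nor captures non-linear relations.
`exposomeRF` implements a six-step machine-learning workflow for this
setting: repeated exposure measurements are condensed into interpretable
per-subject trajectory summaries; a tuned random forest predicts a binary
health outcome from them; permutation importance ranks the exposures; a
cross-validated curve chooses how many top exposures suffice; and partial
dependence (PDP) and accumulated local effects (ALE) curves display the
shape of each retained exposure-outcome relation.

Throughout, the positive class (label 1) is the adverse outcome — e.g.
poor/fair self-perceived health — and class 0 the favourable one; all
sensitivities refer to class 1.

# Step 1: trajectory summaries (AUE and TOE)

For a subject observed at rounds $r_1 < \dots < r_k$ with exposure values
$v_1, \dots, v_k$, the package computes

* **AUE (Area-Under-the-Exposure)** — the time-average of the
  piecewise-linear trajectory,
  $$\mathrm{AUE} = \frac{1}{r_k - r_1} \sum_{i=1}^{k-1}
    \frac{v_i + v_{i+1}}{2}\,(r_{i+1} - r_i),$$
* **TOE (Trend-Of-the-Exposure)** — the unweighted mean of the slopes
  between consecutive observed rounds,
  $$\mathrm{TOE} = \frac{1}{k-1} \sum_{i=1}^{k-1}
    \frac{v_{i+1} - v_i}{r_{i+1} - r_i}.$$

Categorical exposures use the occupancy proportion (fraction of observed
rounds spent in a configured state set) as their AUE analogue and a
direction-sensitive transition indicator (1 if a reference-state
observation is later followed by a target-state observation) as their TOE
analogue. Single-round exposures pass through unchanged.

Several conventions here were genuinely open and are fixed as follows:

* **AUE normalization.** The area is divided by the span of *observed*
  rounds, making it a time-average. This keeps subjects with different
  missingness patterns on one scale; an unnormalized area would scale with
  the number of observed rounds rather than the exposure level.
* **TOE averaging.** Per-pair slopes are averaged unweighted. With
  unequally spaced observed rounds this differs from the end-to-end slope
  $(v_k - v_1)/(r_k - r_1)$; the unweighted mean treats each observed
  transition as one piece of evidence about the direction of change.
* **Single observations.** AUE equals the observed value and TOE is 0.
  This keeps every subject in the feature table rather than discarding
  those with heavy missingness — the point of these summaries is that they
  remain computable under missing rounds.
* **Transitions are directional.** "Reference before target" fires the
  indicator; the reverse order does not. Multiple transitions still yield
  1 (an indicator, not a count).
* **Imputation.** A subject observed in *no* round for an exposure gets
  the cohort median (continuous scales) or mode (indicators), with the
  affected entries recorded in a missingness mask and per-feature counts
  kept for reporting. Model-based imputation is deliberately avoided: the
  forest should not be handed information that leaks across subjects.

# Steps 2-3: the forest and its tuning

The classifier is a classification random forest (CRAN **randomForest**
under the hood) exposed through exactly four tuning parameters: `mtry`
(features sampled per split), `ntree`, `nodesize` (minimum terminal-node
size) and `maxnodes` (maximum terminal nodes, unbounded by default). The
predicted risk is the **vote fraction**: the proportion of trees whose
hard class vote is 1, so risks are multiples of $1/\texttt{ntree}$. This
is intentionally not the average of per-leaf probabilities; the vote
definition is what makes the reduced models and effect curves directly
comparable.

Subjects are split 80/20 into training and test sets with per-class
rounding so both splits preserve the outcome prevalence. Hyperparameters
are chosen by grid search with stratified k-fold cross-validation (default
k = 5) on the training set only, scored by out-of-fold AUC; the same fold
assignment is reused for every grid point so differences are attributable
to the parameters. The default grid is
mtry $\in \{\lfloor\sqrt p\rfloor, \lfloor p/5\rfloor, \lfloor p/3\rfloor\}$,
ntree $\in \{500, 1000\}$, nodesize $\in \{1, 5, 10\}$,
maxnodes $\in \{\infty, 64, 256\}$; exact AUC ties are broken by a
grid-order-independent key (smallest ntree, then largest nodesize, then
smallest maxnodes, then smallest mtry — the cheapest, most regularized
candidate). Class imbalance at ~16% prevalence is left untouched: no
resampling or reweighting is applied.

# Step 4: permutation importance

Variable importance is the raw (unscaled) **mean decrease in accuracy**:
for feature $j$, each tree's accuracy on its own out-of-bag (OOB)
subjects is compared with its accuracy on the same subjects after column
$j$ is permuted, and the per-tree drops are averaged. One fresh
permutation of the whole column is drawn per feature (per repeat) and
every tree is evaluated on its own OOB rows under it; because OOB sets
differ across trees, the values each tree sees differ too. This shared-
permutation scheme costs one forest prediction per feature instead of one
per tree and is equivalent in expectation under row exchangeability.
`n_perm` can be raised to average several permutations. Two exact
properties anchor the implementation: a feature the ensemble never splits
on has MDA exactly 0, and a constant column has MDA exactly 0.

By default the ranking is computed on the **training split only**, so the
held-out AUC of any downstream reduced model remains honest. A
`ranking_on = "full"` option refits on the entire dataset instead — some
analyses prefer the full-data ranking for interpretation — but it is
accompanied by an explicit leakage warning, because features selected
with sight of the test outcomes make test AUCs optimistic.

# Step 5: how many exposures are enough

The number of retained top-ranked exposures $q$ is treated as one more
tuning parameter: for each candidate $q$ the forest is refit on the top-q
features (with `mtry` re-capped at $\min(\texttt{mtry}, q)$) and scored by
k-fold CV AUC with the previously tuned parameters, on one shared fold
assignment. The published workflow picked $q$ visually at the point where
this curve flattens; the package operationalizes that as *the smallest
$q$ within `flattening_epsilon` (default 0.005 AUC) of the curve
maximum*, and always emits the full curve so the visual choice can be
made — or overridden — by a human.

# Step 6: effect curves

**PDP.** For grid value $g$, every subject's feature is set to $g$ while
all other features keep their observed values, and predictions are
averaged. Continuous features use 50 equally spaced grid points inside
the 5th-95th percentile window (clipping avoids reading tail effects off
a handful of subjects); features with at most 10 distinct observed values
(indicators, occupancy proportions over few rounds) use their exact
levels. The outcome prevalence is stored on each curve as the natural
reference line.

**ALE.** The same percentile window is cut into 20 empirical quantile
bins; within a bin the local effect is the mean prediction difference
between the bin's upper and lower edge for the subjects observed in that
bin — so the model is only ever queried near feature combinations that
actually occur, which is what makes ALE robust to correlated exposures.
Local effects are accumulated across bins and centered so the
data-weighted mean of the curve is zero (an invariant the tests check to
1e-12). Duplicate quantile edges from heavy ties are merged and logged;
binary features fall back to a centered two-level contrast.

PDPs give the effect on the risk scale; ALE curves validate their shapes.
`curve_concordance()` quantifies the qualitative check that the two agree
in slope sign segment by segment.

# Evaluation and ablation

`evaluate_model()` reports the Mann-Whitney AUC (ties counted 1/2) with a
DeLong 95% interval (the variance of the placement values; the interval
is truncated to [0,1] and matches **pROC**'s DeLong interval to machine
precision in the cross-check tests). The "optimal" ROC threshold
maximizes sensitivity + specificity (Youden); exact ties break toward
the smaller threshold, favouring sensitivity for the adverse class.
Metrics at the predefined 0.5 cut-off, calibration-in-the-large (mean
predicted risk minus prevalence) and a decile calibration curve (quantile
bins, merged on ties) complete the report. Domain ablation refits the
whole tuned pipeline once per exposome domain with that domain's features
removed, on the same split and seeds; each ablated model is re-tuned by
default, since a fixed tuning could favour the full model.

# The synthetic cohort generator

Because the motivating cohort data are not publicly available, the
package ships a generator whose defaults emulate that study's *shape*:
3419 subjects, exposures measured in rounds 1-5 and the outcome afterwards,
51 exposures (45 multi-round, 6 single-round) across the four exposome
domains yielding exactly 96 summary features, and an intercept calibrated
by root-finding so the outcome prevalence is 0.16. Continuous
trajectories follow a random-intercept/random-slope model with
independent noise — the simplest process whose AUE and TOE map directly
onto the latent intercepts and slopes — and categorical exposures follow
Markov chains. Nine planted signal features (a mix of AUE and TOE
summaries, including one u-shaped effect on BMI-like AUE and one
marital-transition indicator, with linear coefficients of 0.45-0.60 on
the log-odds scale per SD of the standardized true summary) drive the
outcome; everything else is noise. Missingness combines per-round MCAR
rates rising from 2% to 12% with a monotone dropout hazard rising to 5%
per round; an outcome-linked dropout option exists but is off by default.
All randomness flows from one seed through named substreams, so any stage
is reproducible in isolation.

What the generator deliberately does **not** emulate: the real marginal
distributions of the exposures, correlations *between* exposures (each is
drawn independently), informative censoring, and outcomes that depend on
round-level values rather than trajectory summaries. The last point is a
stated validation premise: the outcome is generated from the true AUE/TOE
values, which makes trajectory summaries the correct representation by
construction. Passing recovery tests therefore demonstrates that the
pipeline finds what is there under the declared data model — not that
AUE/TOE are sufficient summaries of any real cohort.

# Validation design and problem sizes

The test suite validates each stage against an independent oracle:
dense numerical integration and brute-force slope means for AUE/TOE
(1000 random trajectories, 1e-9 relative tolerance), exhaustive
enumeration over all labelings of small score sets for AUC and the
Youden threshold, closed forms on exact-function stub models for PDP/ALE,
null simulations (permuted labels: test AUC at chance, MDA distribution
straddling zero), and planted-signal recovery on the default cohort
(at least 7 of the 9 planted features in the selected top-q set in at
least 9 of 10 seeds). Validation runs use `ntree = 200`, 2-5 CV folds
and thinned q-grids; these sizes were chosen so the whole suite runs on
one CPU in minutes while keeping every Monte-Carlo margin comfortable,
and they are not the recommended analysis settings (the defaults of
`run_config()` are).

# Known limitations

* AUE and TOE compress trajectories to level and trend; oscillating or
  threshold-crossing trajectories with equal level and trend are
  indistinguishable. Spline or functional-PCA representations are out of
  scope.
* Permutation importance is marginal: correlated exposures share credit,
  and the duplicated-feature tests demonstrate the dilution directly.
  Conditional importance is not implemented.
* The q-selection rule inherits CV noise; `flattening_epsilon` trades
  parsimony against AUC and should be read together with the emitted
  curve, not in place of it.
* No survival outcomes, no probability calibration post-processing, no
  alternative learners.
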