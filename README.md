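# exposomeRF

Random-forest identification of longitudinal exposome predictors of a
binary health outcome.

## The problem

Longitudinal cohorts measure dozens of exposures — demographic, lifestyle,
environmental, biological — repeatedly over decades, and ask which of them
predict a later health outcome. With ~100 candidate exposures, unbalanced
panels (subjects miss rounds), and mostly non-linear relations, classical
per-exposure regression is a poor fit. `exposomeRF` implements a six-step
machine-learning workflow for epidemiologists working with such data:

1. **Summarize trajectories.** Each exposure measured in rounds
   $r_1 < \dots < r_k$ with values $v_1,\dots,v_k$ becomes two per-subject
   features:
   the *Area-Under-the-Exposure*
   (time-averaged level,
   $\mathrm{AUE} = \frac{1}{r_k-r_1}\sum_i \frac{v_i+v_{i+1}}{2}(r_{i+1}-r_i)$)
   and the *Trend-Of-the-Exposure*
   (mean slope, $\mathrm{TOE} = \frac{1}{k-1}\sum_i \frac{v_{i+1}-v_i}{r_{i+1}-r_i}$).
   Categorical exposures use state-occupancy proportions and
   reference-to-target transition indicators. Both are well defined under
   missing rounds.
2. **Random forest.** A classification forest predicts the outcome from
   the summary features; the predicted risk is the fraction of trees
   voting for the adverse class.
3. **Tuning.** Stratified 80/20 split; grid search over `mtry`, `ntree`,
   `nodesize`, `maxnodes` with stratified 5-fold CV on the training data,
   scored by AUC.
4. **Ranking.** Exposures are ranked by raw mean decrease in accuracy
   (MDA): the drop in per-tree out-of-bag accuracy when the feature's
   column is permuted.
5. **How many exposures?** The number of retained top-ranked exposures
   *q* is treated as a tuning parameter: a cross-validated AUC-versus-q
   curve is computed and the smallest q within a small epsilon of the
   curve's maximum is selected ("flattening" rule).
6. **Effect shapes.** Partial dependence plots (PDP) and accumulated
   local effects (ALE) curves are computed for the selected exposures,
   restricted to the 5th-95th percentile of each feature.

Discrimination (AUC with DeLong 95% CI), sensitivity/specificity at the
Youden-optimal and at the 0.5 threshold, calibration-in-the-large, decile
calibration curves, and per-domain ablation models round out the
evaluation.

Because cohort data of this kind are typically not shareable, the package
includes a synthetic-cohort generator with known ground truth
(`default_paper_like_spec()`: 3419 subjects, 5 rounds, 96 summary
features across 4 domains, 16% outcome prevalence, 9 planted signals,
round-dependent missingness) so the entire pipeline is testable end to
end.

## Worked example

```r
library(exposomeRF)

spec <- default_paper_like_spec(seed = 7)
gen  <- generate_cohort(spec)           # cohort + ground-truth ledger

config <- run_config(
  tuning_grid = list(rf_params(9,  ntree = 200, nodesize = 5),
                     rf_params(32, ntree = 200, nodesize = 5)),
  q_grid = c(1, 2, 4, 6, 9, 12, 24, 96), cv_folds = 3, seed = 7)

res <- run_pipeline(gen$cohort, config = config)
print(res)
print(res$evaluation_full)
as.data.frame(res$q_curve)
recovery_report(gen$ledger, res)
write_report_bundle(res, "results")     # CSV tables + JSON manifest
```

Output (abridged):

```
[exposomeRF] step 1: summarizing trajectories
[exposomeRF] steps 2-3: split, tune (2 combinations), fit
[exposomeRF]   all-feature test AUC 0.751
[exposomeRF] step 4: permutation importance (ranking on train data)
[exposomeRF] step 5: q-performance curve over 8 values
[exposomeRF]   selected q = 9; reduced-model test AUC 0.793 (vs 0.751 full)
[exposomeRF] step 6: PDP and ALE curves for the top 9 features
[exposomeRF] domain ablation

Six-step pipeline result
  features: 96; train/test: 2736/683
  all-feature test AUC 0.751 (95% CI 0.699-0.803)
  selected q = 9; reduced-model test AUC 0.793
  ablation rows: 5; effect curves: 18

AUC 0.751 (95% CI 0.699-0.803), n = 683
optimal threshold 0.237: sens 0.584, spec 0.821
at 0.5: sens 0.142, spec 0.988, accuracy 0.848
calibration-in-the-large: mean risk 0.173 vs prevalence 0.165

   q    cv_auc selected
1  1 0.6001237    FALSE
2  2 0.6535429    FALSE
3  4 0.7221198    FALSE
4  6 0.7748777    FALSE
5  9 0.8072182     TRUE
6 12 0.8056952    FALSE
7 24 0.7995053    FALSE
8 96 0.7850382    FALSE

planted features recovered in top-q: 9 of 9
```

Reading it: the all-feature forest separates poor from good outcomes on
held-out subjects (test AUC with its DeLong interval); the q-curve rises
steeply while the strongest planted predictors enter and flattens once
the planted signal is exhausted, so the selection rule keeps a small
reduced model whose test AUC is close to the full model's; mean predicted
risk tracks the observed prevalence (calibration-in-the-large); and the
recovery report confirms which of the 9 planted features the selected set
found. PDP/ALE tables for each selected feature are in
`res$effect_curves` and in `results/effect_curves.csv`.

A thin command-line front end with `simulate` / `summarize` / `run` /
`report` subcommands is installed at `inst/scripts/exposome_pipeline.R`.

## Package layout

| Area | Functions |
|---|---|
| I/O & config | `read_cohort`, `write_cohort`, `read_schema`, `run_config`, `write_report_bundle` |
| Trajectory summaries | `aue_continuous`, `toe_continuous`, `aue_categorical`, `toe_categorical`, `summarize_cohort` |
| Forest | `stratified_split`, `default_tuning_grid`, `tune_forest`, `fit_forest`, `predict_risk` |
| Importance & q | `permutation_importance`, `q_performance_curve`, `select_q` |
| Effect curves | `pdp`, `ale`, `curve_concordance` |
| Evaluation | `roc_auc`, `auc_ci`, `optimal_threshold`, `evaluate_model`, `domain_ablation` |
| Synthetic cohorts | `synthetic_spec`, `default_paper_like_spec`, `generate_cohort`, `recovery_report` |
| Orchestration | `run_pipeline` |

See the vignette (`vignettes/exposome-pipeline.Rmd`) for the scientific
rationale behind every numerical choice.
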