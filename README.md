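# trajmi

Local multiple imputation and forecasting of irregularly monitored
biomarker trajectories.

## What this is for

Longitudinal biomarkers measured under routine care — BCR::ABL1 transcript
levels in chronic myeloid leukemia being the motivating case — arrive
irregularly: visits drift around the guideline 3-month schedule, get
skipped (most often by patients doing well), and assay formats change over
time. `trajmi` is for biostatisticians and clinical data scientists who
need complete, regularly spaced trajectories from such records, and
short-horizon forecasts with honest uncertainty.

The core statistic is a *local, windowed multiple imputation*: raw values
are standardized as log-ratios against format-specific baseline medians,

```
y_ij = log( raw_ij / median_f(baseline raws) ),
```

aligned to a 90-day grid (nearest observation within a closed 45-day
window, one observation per grid point), and missing grid cells are filled
from interval-specific linear models

```
Y_t = alpha_t + beta_t' Z_t + gamma_t' X + eps,   eps ~ N(0, sigma_t^2)
```

where `Z_t` holds the two lagged and two lead grid values (de-meaned per
column) and `X` the baseline covariates. Sweeps run in ascending `t`
(Gibbs-style) through 15 burn-in iterations, then `m = 10` completed
datasets are drawn, each adding `N(0, sigma_t^2)` residual noise.
Medication adherence enters as a CMA9 availability trajectory (fraction of
days covered by dispensed supply per 90-day interval, with carry-over).
Forecasts of `Y_{t+1}` and `Y_{t+2}` come from gradient-boosted trees and
a small recurrent network under two feature sets — *full information*
(`Y_t, Y_{t-1}, Y_{t-2}`, adherence, age, time since diagnosis) and
*skipped last visit* (drops `Y_{t-1}`, adds the 6-month change
`Y_t - Y_{t-2}`, emulating an extended monitoring interval) — and are
pooled across imputations with Rubin's rules:

```
Qbar = mean(Q_k),  W = mean(W_k),  B = var(Q_k),  T = W + (1 + 1/m) B.
```

Because real cohorts of this kind are access-restricted, the package ships
a calibrated synthetic-cohort generator (`simulate_cohort()`) so the whole
workflow is testable end to end.

## Worked example

```r
library(trajmi)

co  <- simulate_cohort(sim_config(n_patients = 200, seed = 1))
co
#> Synthetic monitoring cohort
#>   patients:      200
#>   measurements:  3024 (74.8% of grid cells observed)
#>   value summary: mean -4.31, sd 2.81, range (-8.50, 1.10)

med <- format_median_table(co$measurements, co$treatment)
al  <- align_to_grid(standardize(co$measurements, med, co$treatment))
mean(is.na(al$value))      # 23.6% of grid cells missing

imp <- run_multiple_imputation(al, co$covariates, burnin = 15, m = 10, seed = 1)
imp
#> Multiply imputed grids: m = 10, burn-in = 15, 932 imputed cells per dataset

tail(convergence_summary(imp), 3)
#>    iteration max_abs_change max_change_se
#> 1:        13          0.446          1.30
#> 2:        14          0.755          1.17
#> 3:        15          0.633          1.38
```

`max_change_se` is the largest between-iteration coefficient change in
standard-error units; values near 1–2 are pure resampling noise (the
package treats < 6 as stabilized), so the chain has converged. A
mask-and-recover check on the same cohort shows the local models earn
their keep against naive column-mean filling:

```r
mask_and_recover(co$true_grid, co$covariates, mask_fraction = 0.1, seed = 1)
#> RMSE 0.834 vs column-mean 2.251 (95% spread coverage 0.78)
```

The full pipeline (simulate -> preprocess -> adherence -> impute ->
forecast -> evaluate) runs from one config and writes plain CSVs plus a
machine-readable summary:

```r
cfg <- pipeline_config(out_dir = "demo", seed = 1, n_patients = 100,
                       burnin = 15, m = 5, ensemble_B = 5,
                       learner_hyperparams = list(
                         xgboost = list(nrounds = 150, max_depth = 3, eta = 0.1),
                         rnn = list(hidden = 16, epochs = 150)))
run_all(cfg)
jsonlite::fromJSON("demo/summary.json")$overall
```

| learner | spec    | horizon | rmse  | se    | rmse/sd |
|---------|---------|---------|-------|-------|---------|
| xgboost | full    | 1       | 0.989 | 0.062 | 0.364   |
| rnn     | full    | 1       | 0.959 | 0.056 | 0.353   |
| xgboost | full    | 2       | 1.168 | 0.061 | 0.430   |
| rnn     | full    | 2       | 1.131 | 0.057 | 0.417   |
| xgboost | skipped | 1       | 1.009 | 0.066 | 0.372   |
| rnn     | skipped | 1       | 0.995 | 0.050 | 0.367   |
| xgboost | skipped | 2       | 1.176 | 0.063 | 0.433   |
| rnn     | skipped | 2       | 1.183 | 0.094 | 0.436   |

(`se` is the Rubin total-variance standard error of the pooled RMSE; the
run above completes in about 4 minutes on one CPU.)  Pooled RMSEs sit well
below the cohort SD of the standardized values (here 2.714), horizon-2
errors exceed horizon-1, and the full-information feature set is at least
as accurate as skipped-last-visit in every cell (`$orderings` reports all
eight flags `TRUE`) — the qualitative pattern expected of this design. Per-interval RMSEs are in
`demo/rmse_by_time.csv`; pooled per-patient predictions with Rubin
intervals in `demo/pooled_predictions.csv`.

A command-line wrapper is included:

```sh
Rscript inst/cli/trajmi.R run-all --seed 1 --out-dir demo
```

## Package layout

- `R/simulate.R` — calibrated synthetic cohort generator
- `R/preprocess.R` — standardization and grid alignment
- `R/adherence.R` — CMA9 adherence trajectories
- `R/impute.R` — the local windowed multiple-imputation engine
- `R/learners.R`, `R/forecast.R` — feature sets, boosted trees, recurrent net
- `R/evaluate.R` — Rubin pooling and RMSE reporting
- `R/schemas.R`, `R/pipeline.R` — CSV schemas, stage runner, CLI
- `vignettes/local-imputation-forecasting.Rmd` — the methods vignette
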