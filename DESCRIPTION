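Package: trajmi
Title: Local Multiple Imputation and Forecasting of Irregularly Monitored
    Biomarker Trajectories
Version: 0.1.0
Authors@R:
    person("Jordan", "Carter", email = "jcarter@example.org",
           role = c("aut", "cre"))
Description: Tools for turning irregular real-world longitudinal biomarker
    monitoring into complete, regularly spaced trajectories and short-horizon
    forecasts.  Raw assay values are log-standardized against format-specific
    baseline medians and aligned to a 90-day grid with a 45-day matching
    window; missing grid cells are filled by a local, windowed multiple
    imputation algorithm (interval-specific linear models on two lead and two
    lag values plus baseline covariates, Gaussian residual draws, burn-in
    sweeps, m completed datasets); medication adherence trajectories are
    computed with the CMA9 availability metric from pharmacy dispensation
    records; gradient-boosted trees and a small recurrent network forecast
    values one and two intervals ahead; and accuracy is pooled across
    imputations with Rubin's rules.  A synthetic-cohort generator emulating
    BCR::ABL1 monitoring in chronic myeloid leukemia makes the whole pipeline
    testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
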