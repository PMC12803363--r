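## Synthetic cohort generator -------------------------------------------------
##
## Emulates routine molecular monitoring of a slowly-treated chronic disease:
## standardized log-ratio biomarker values fall sharply after therapy start,
## then plateau at a patient-specific low level; visits are scheduled every
## `grid_days` but jittered and sometimes skipped (more often when the value is
## low, i.e. when the patient is doing well); pharmacy fills generate an
## adherence history.  Defaults are calibrated once so the marginal value
## distribution matches the published cohort summaries (mean ~ -4.3,
## SD ~ 2.83, range ~ (-8.3, 1.1)).

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set consumed by [simulate_cohort()].
#' The latent per-patient trajectory on the standardized (log-ratio) scale is
#' a linear decline from `baseline` to a patient-specific `plateau`,
#'
#' \deqn{y_i(d) = \max(\mathrm{plateau}_i,\; \mathrm{baseline}_i - \mathrm{rate}_i \, d) + e_{i,t},}
#'
#' with AR(1) fluctuation \eqn{e_{i,t}} (stationary SD `noise_sd`, lag-1
#' correlation `ar1_rho`), clipped to `clip_range`.  Visits occur at multiples
#' of `grid_days` plus uniform integer jitter and are skipped independently
#' with probability
#' \eqn{\mathrm{logit}^{-1}(\mathrm{logit}(\texttt{skip\_prob\_base}) + \texttt{skip\_prob\_value\_coef}\, y)},
#' so missingness is MAR given the current latent value.  Per-patient
#' adherence propensities are Beta(`adherence_alpha`, `adherence_beta`).
#'
#' @param n_patients number of patients (>= 2).
#' @param followup_days maximum administrative follow-up in days; each
#'   patient's own follow-up is uniform on `[min_followup_days, followup_days]`.
#' @param grid_days scheduled visit interval in days (default 90).
#' @param baseline_mean,baseline_sd standardized value at therapy start.
#'   Centered at 0 because the standardization is a log-ratio against the
#'   cohort's baseline median.
#' @param plateau_mean,plateau_sd long-run patient-specific level of the
#'   shallow-response subgroup (truncated normal, truncation at `clip_range`).
#' @param deep_response_prob,deep_plateau_mean,deep_plateau_sd a fraction of
#'   patients reach a deep molecular response with plateaus near the assay
#'   floor; the plateau distribution is the two-component mixture.  This
#'   reproduces the strongly left-spread marginal distribution seen in real
#'   monitoring cohorts (first quartile near the floor, median much higher).
#' @param decline_rate_mean,decline_rate_sd decline speed in standardized
#'   units per day (truncated below at `1e-4`).
#' @param noise_sd,ar1_rho stationary SD and lag-1 correlation of the AR(1)
#'   visit-to-visit fluctuation.
#' @param clip_range length-2 numeric; latent values are clipped here.
#' @param visit_jitter_days maximum absolute integer jitter of a visit day
#'   around its scheduled grid day (must be < `grid_days / 2`).
#' @param skip_prob_base baseline visit-skip probability (at y = 0).
#' @param skip_prob_value_coef per-unit effect of the current standardized
#'   value on the skip log-odds; negative values make deep responders skip
#'   more, mimicking clinicians extending intervals for low-risk patients.
#' @param adherence_alpha,adherence_beta Beta shape parameters of the
#'   per-patient refill propensity.
#' @param min_followup_days shortest per-patient follow-up.
#' @param fill_supply_days days of drug supplied per pharmacy fill.
#' @param format_medians named positive numeric vector: reference median raw
#'   value per assay format; raw values are `median * exp(y)`.
#' @param seed master integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200L,
                       followup_days = 2700L,
                       grid_days = 90L,
                       baseline_mean = 0,
                       baseline_sd = 0.45,
                       plateau_mean = -2.8,
                       plateau_sd = 1.2,
                       deep_response_prob = 0.52,
                       deep_plateau_mean = -8.2,
                       deep_plateau_sd = 0.3,
                       decline_rate_mean = 0.011,
                       decline_rate_sd = 0.004,
                       noise_sd = 0.8,
                       ar1_rho = 0.3,
                       clip_range = c(-8.5, 1.1),
                       visit_jitter_days = 10L,
                       skip_prob_base = 0.20,
                       skip_prob_value_coef = -0.08,
                       adherence_alpha = 5,
                       adherence_beta = 1.2,
                       min_followup_days = 720L,
                       fill_supply_days = 30L,
                       format_medians = c(IS_PCT = 45, RATIO = 0.62),
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), followup_days = as.integer(followup_days),
    grid_days = as.integer(grid_days), baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, plateau_mean = plateau_mean,
    plateau_sd = plateau_sd, deep_response_prob = deep_response_prob,
    deep_plateau_mean = deep_plateau_mean, deep_plateau_sd = deep_plateau_sd,
    decline_rate_mean = decline_rate_mean,
    decline_rate_sd = decline_rate_sd, noise_sd = noise_sd, ar1_rho = ar1_rho,
    clip_range = as.numeric(clip_range), visit_jitter_days = as.integer(visit_jitter_days),
    skip_prob_base = skip_prob_base, skip_prob_value_coef = skip_prob_value_coef,
    adherence_alpha = adherence_alpha, adherence_beta = adherence_beta,
    min_followup_days = as.integer(min_followup_days),
    fill_supply_days = as.integer(fill_supply_days),
    format_medians = format_medians, seed = as.integer(seed))

  num <- unlist(cfg[c("baseline_mean", "baseline_sd", "plateau_mean", "plateau_sd",
                      "decline_rate_mean", "decline_rate_sd", "noise_sd", "ar1_rho",
                      "skip_prob_base", "skip_prob_value_coef",
                      "adherence_alpha", "adherence_beta")])
  stop_if(any(!is.finite(num)), "non-finite value in simulation config")
  stop_if(cfg$n_patients < 2L, "n_patients must be >= 2")
  stop_if(cfg$grid_days <= 0L, "grid_days must be positive")
  stop_if(any(c(cfg$baseline_sd, cfg$plateau_sd, cfg$decline_rate_sd, cfg$noise_sd) < 0),
          "standard deviations must be non-negative")
  stop_if(cfg$skip_prob_base < 0 || cfg$skip_prob_base > 1,
          "skip_prob_base must be a probability in [0, 1]")
  stop_if(cfg$deep_response_prob < 0 || cfg$deep_response_prob > 1,
          "deep_response_prob must be a probability in [0, 1]")
  stop_if(cfg$deep_plateau_sd < 0, "deep_plateau_sd must be non-negative")
  stop_if(abs(cfg$ar1_rho) >= 1, "ar1_rho must be in (-1, 1)")
  stop_if(cfg$visit_jitter_days < 0 || cfg$visit_jitter_days >= cfg$grid_days / 2,
          "visit_jitter_days must lie in [0, grid_days/2)")
  stop_if(length(cfg$clip_range) != 2L || cfg$clip_range[1] >= cfg$clip_range[2],
          "clip_range must be an increasing length-2 numeric")
  stop_if(any(cfg$format_medians <= 0) || is.null(names(cfg$format_medians)),
          "format_medians must be a named positive vector")
  stop_if(cfg$adherence_alpha <= 0 || cfg$adherence_beta <= 0,
          "adherence Beta shapes must be positive")
  stop_if(cfg$min_followup_days > cfg$followup_days,
          "min_followup_days exceeds followup_days")
  structure(cfg, class = "sim_config")
}

## truncated-normal draw by rejection; falls back to clamping after 100 tries
rtnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:100) {
    x <- rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

## Internal refill process using the *current* RNG stream.  First fill always
## occurs on day 0 (therapy start); each subsequent due refill happens with
## probability `propensity`, otherwise a gap of `miss_delay` days opens.
sim_dispensations_stream <- function(propensity, followup_days, fill_supply_days,
                                     miss_delay = fill_supply_days) {
  fills <- integer(0)
  d <- 0L
  first <- TRUE
  while (d < followup_days) {
    take <- first || runif(1L) < propensity
    first <- FALSE
    if (take) {
      fills <- c(fills, d)
      d <- d + fill_supply_days
    } else {
      d <- d + as.integer(miss_delay)
    }
  }
  data.table(fill_day = fills,
             days_supplied = rep(as.integer(fill_supply_days), length(fills)))
}

#' Simulate a pharmacy dispensation history
#'
#' One fill always occurs at day 0; every subsequent due refill occurs with
#' probability `adherence_propensity`, and a missed refill opens a gap of
#' `miss_delay` days before the next attempt.  Propensity 1 yields gap-free
#' supply.
#'
#' @param adherence_propensity refill probability in `[0, 1]`.
#' @param followup_days observation window length in days.
#' @param fill_supply_days days supplied per fill.
#' @param miss_delay gap in days after a missed refill (default one supply).
#' @param seed integer seed.
#' @return `data.table` with columns `fill_day`, `days_supplied`.
#' @export
simulate_dispensations <- function(adherence_propensity, followup_days,
                                   fill_supply_days = 30L,
                                   miss_delay = fill_supply_days, seed = 1L) {
  stop_if(adherence_propensity < 0 || adherence_propensity > 1,
          "adherence_propensity must be in [0, 1]")
  stop_if(fill_supply_days <= 0, "fill_supply_days must be positive")
  set.seed(as.integer(seed))
  sim_dispensations_stream(adherence_propensity, followup_days,
                           fill_supply_days, miss_delay)
}

#' Simulate a synthetic monitoring cohort
#'
#' Generates a complete latent trajectory grid, irregular raw measurements,
#' dispensation records and baseline covariates for `config$n_patients`
#' patients.  Each patient uses an independent pseudo-random stream derived
#' from `(seed, patient index)`, so cohorts are reproducible and unaffected by
#' patient reordering; within a stream all random quantities are drawn up
#' front in a fixed order, which makes the missingness pattern monotone in
#' `skip_prob_base` under a shared seed.
#'
#' The baseline visit (t = 0) is always kept, and a patient left with fewer
#' than two kept visits has the t = 1 visit restored, enforcing the cohort
#' rule that every patient contributes at least two measurements.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `true_grid` (complete grid: `patient_id`, `t_index`, `value`),
#'   `measurements` (`patient_id`, `day`, `raw_value`, `assay_format`, plus
#'   the simulator-side standardized `std_value` for oracle tests),
#'   `dispensations`, `covariates`, `treatment` and `seed_used`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  grids <- meas <- disp <- covs <- vector("list", cfg$n_patients)
  fmts <- names(cfg$format_medians)

  for (i in seq_len(cfg$n_patients)) {
    set.seed(derive_seed(cfg$seed, i))
    pid <- sprintf("P%04d", i)

    ## -- patient-level draws, fixed order ------------------------------------
    baseline <- rtnorm1(cfg$baseline_mean, cfg$baseline_sd,
                        cfg$clip_range[1], cfg$clip_range[2])
    deep <- runif(1L) < cfg$deep_response_prob
    plateau <- if (deep)
      rtnorm1(cfg$deep_plateau_mean, cfg$deep_plateau_sd,
              cfg$clip_range[1], cfg$clip_range[2])
    else
      rtnorm1(cfg$plateau_mean, cfg$plateau_sd,
              cfg$clip_range[1], cfg$clip_range[2])
    rate <- rtnorm1(cfg$decline_rate_mean, cfg$decline_rate_sd, 1e-4, Inf)
    fup <- as.integer(round(runif(1L, cfg$min_followup_days, cfg$followup_days)))
    propensity <- rbeta(1L, cfg$adherence_alpha, cfg$adherence_beta)
    age <- max(18.5, rnorm(1L, 54.6, 16.5))
    bmi <- min(60, max(15, rnorm(1L, 29.4, 6.6)))
    sex <- sample(c("M", "F"), 1L, prob = c(0.61, 0.39))
    treat <- sample(c("imatinib", "dasatinib", "nilotinib"), 1L,
                    prob = c(0.80, 0.16, 0.04))
    fmt <- sample(fmts, 1L)

    Ti <- fup %/% cfg$grid_days
    tt <- 0:Ti
    z <- rnorm(Ti + 1L)
    jit <- if (cfg$visit_jitter_days > 0)
      sample(seq(-cfg$visit_jitter_days, cfg$visit_jitter_days), Ti + 1L, replace = TRUE)
    else rep(0L, Ti + 1L)
    u_skip <- runif(Ti + 1L)
    ## (RNG use below this point: dispensation stream only)

    ## -- latent trajectory ----------------------------------------------------
    mean_t <- pmax(plateau, baseline - rate * cfg$grid_days * tt)
    e <- numeric(Ti + 1L)
    e[1] <- cfg$noise_sd * z[1]
    if (Ti >= 1L) for (k in 2:(Ti + 1L))
      e[k] <- cfg$ar1_rho * e[k - 1] + cfg$noise_sd * sqrt(1 - cfg$ar1_rho^2) * z[k]
    y <- pmin(pmax(mean_t + e, cfg$clip_range[1]), cfg$clip_range[2])

    ## -- visit process --------------------------------------------------------
    p_skip <- plogis(qlogis(cfg$skip_prob_base) + cfg$skip_prob_value_coef * y)
    keep <- u_skip >= p_skip
    keep[1] <- TRUE                      # baseline visit always collected
    if (sum(keep) < 2L && Ti >= 1L) keep[2] <- TRUE
    days <- as.integer(cfg$grid_days * tt + jit)
    days[1] <- 0L

    grids[[i]] <- data.table(patient_id = pid, t_index = tt, value = y)
    meas[[i]] <- data.table(patient_id = pid, day = days[keep],
                            raw_value = cfg$format_medians[[fmt]] * exp(y[keep]),
                            assay_format = fmt, std_value = y[keep],
                            t_index = tt[keep])
    disp[[i]] <- cbind(patient_id = pid,
                       sim_dispensations_stream(propensity, fup, cfg$fill_supply_days))
    covs[[i]] <- data.table(patient_id = pid, age_at_dx = age, bmi = bmi,
                            sex = sex, first_line_treatment = treat,
                            adherence_propensity = propensity,
                            followup_days = fup)
  }

  out <- list(true_grid = rbindlist(grids), measurements = rbindlist(meas),
              dispensations = rbindlist(disp), covariates = rbindlist(covs),
              treatment = data.table(patient_id = sprintf("P%04d", seq_len(cfg$n_patients)),
                                     treatment_start_day = 0L),
              config = cfg, seed_used = cfg$seed)
  structure(out, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic monitoring cohort\n")
  cat(sprintf("  patients:      %d\n", nrow(x$covariates)))
  cat(sprintf("  measurements:  %d (%.1f%% of grid cells observed)\n",
              nrow(x$measurements),
              100 * nrow(x$measurements) / nrow(x$true_grid)))
  cat(sprintf("  value summary: mean %.2f, sd %.2f, range (%.2f, %.2f)\n",
              mean(x$true_grid$value), sd(x$true_grid$value),
              min(x$true_grid$value), max(x$true_grid$value)))
  invisible(x)
}
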