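## Independent oracles and shared fixtures for the test suite.

library(data.table)

## Brute-force alignment oracle: enumerate every (grid point, observation)
## pair, then repeatedly pick the globally smallest remaining distance
## (ties: earlier observation day, then earlier grid index), never reusing
## either side.  Naive O(n^3) loop, deliberately different from the package
## implementation.
oracle_align <- function(days, values, grid_days, window, t_max) {
  pairs <- expand.grid(t = 0:t_max, j = seq_along(days))
  pairs$dist <- abs(days[pairs$j] - grid_days * pairs$t)
  pairs <- pairs[pairs$dist <= window, , drop = FALSE]
  out <- rep(NA_real_, t_max + 1L)
  used_j <- logical(length(days))
  used_t <- logical(t_max + 1L)
  while (nrow(pairs) > 0) {
    d <- pairs$dist
    cand <- which(d == min(d))
    if (length(cand) > 1) {  # earlier observation day, then earlier grid index
      od <- days[pairs$j[cand]]
      cand <- cand[od == min(od)]
      if (length(cand) > 1) cand <- cand[which.min(pairs$t[cand])]
    }
    t <- pairs$t[cand[1]]; jj <- pairs$j[cand[1]]
    out[t + 1L] <- values[jj]
    used_t[t + 1L] <- TRUE; used_j[jj] <- TRUE
    pairs <- pairs[pairs$t != t & pairs$j != jj, , drop = FALSE]
  }
  out
}

## Day-resolution CMA9 oracle: walk the fills in order, extending a boolean
## covered/uncovered day array with carry-over.
oracle_cma9 <- function(fill_day, days_supplied, observation_end, grid_days = 90L) {
  covered <- logical(observation_end)
  avail <- 0
  for (k in seq_along(fill_day)) {
    s <- max(fill_day[k], avail)
    e <- s + days_supplied[k]
    avail <- e
    if (s < observation_end)
      covered[(s + 1):min(e, observation_end)] <- TRUE
  }
  n_int <- ceiling(observation_end / grid_days)
  vapply(0:(n_int - 1L), function(t) {
    d <- covered[(t * grid_days + 1):min((t + 1) * grid_days, observation_end)]
    min(sum(d) / grid_days, 1)
  }, numeric(1))
}

## small cohort fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- simulate_cohort(sim_config(n_patients = 120, seed = 20))
  .fixtures$cohort
}

cohort_aligned <- function(co) {
  med <- format_median_table(co$measurements, co$treatment)
  align_to_grid(standardize(co$measurements, med, co$treatment))
}

cohort_adherence <- function(co, grid_days = 90L) {
  ends <- setNames(as.list((co$covariates$followup_days %/% grid_days + 1L) * grid_days),
                   co$covariates$patient_id)
  compute_adherence(co$dispensations, observation_end = ends, grid_days = grid_days)
}

## small learner settings used throughout the suite (full-size defaults are
## exercised implicitly through the same code path)
small_hp <- list(
  xgboost = list(nrounds = 80L, max_depth = 3L, eta = 0.1),
  rnn = list(hidden = 10L, epochs = 100L))
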