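dtab <- data.table::data.table

test_that("local model recovers exact linear data with zero residual SD", {
  set.seed(1)
  n <- 60
  lead1 <- rnorm(n, 0, 2)
  Z <- cbind(lag2 = 0, lag1 = 0, lead1 = lead1, lead2 = 0)
  y <- 1 + 0.5 * lead1
  fit <- fit_local_model(y, Z)
  expect_false(fit$degenerate)
  expect_equal(unname(fit$coef["(Intercept)"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$coef["lead1"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(fit$coef[c("lag2", "lag1", "lead2")]), c(0, 0, 0))
  expect_equal(fit$sigma, 0, tolerance = 1e-7)
})

test_that("under-determined fits are flagged degenerate", {
  Z <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, c("lag2", "lag1", "lead1", "lead2")))
  fit <- fit_local_model(rnorm(3), Z)
  expect_true(fit$degenerate)
  expect_error(impute_cell(fit, rep(0, 4)), "degenerate")
})

test_that("residual SD uses denominator n - p - 1 on full-rank designs", {
  set.seed(2)
  n <- 40
  Z <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, c("lag2", "lag1", "lead1", "lead2")))
  y <- rnorm(n)
  fit <- fit_local_model(y, Z)
  res <- y - (fit$coef[1] + Z %*% fit$coef[2:5])
  expect_equal(fit$sigma, sqrt(sum(res^2) / (n - 5)), tolerance = 1e-10)
})

test_that("impute_cell is the linear predictor plus a seeded Gaussian draw", {
  set.seed(3)
  lead1 <- rnorm(50, 0, 2)
  fit <- fit_local_model(1 + 0.5 * lead1,
                         cbind(lag2 = 0, lag1 = 0, lead1 = lead1, lead2 = 0))
  ## sigma = 0, window at the mean: exactly alpha
  expect_equal(impute_cell(fit, c(0, 0, 0, 0)), 1, tolerance = 1e-7)
  ## missing window entries count as the de-meaned mean (0)
  expect_equal(impute_cell(fit, c(NA, NA, NA, NA)), 1, tolerance = 1e-7)
  ## determinism under a fixed seed
  fit$sigma <- 0.7
  set.seed(42); a <- impute_cell(fit, c(0, 0, 1, 0))
  set.seed(42); b <- impute_cell(fit, c(0, 0, 1, 0))
  expect_identical(a, b)
})

test_that("imputation draws match the stated noise model (Monte Carlo)", {
  set.seed(4)
  lead1 <- rnorm(80, 0, 2)
  fit <- fit_local_model(2 - 0.8 * lead1 + rnorm(80, 0, 0.5),
                         cbind(lag2 = 0, lag1 = 0, lead1 = lead1, lead2 = 0))
  eta <- unname(fit$coef["(Intercept)"] + fit$coef["lead1"])
  set.seed(5)
  draws <- replicate(10000, impute_cell(fit, c(0, 0, 1, 0)))
  expect_lt(abs(mean(draws) - eta), 4 * fit$sigma / 100)
  expect_lt(abs(sd(draws) / fit$sigma - 1), 0.05)
})

## noiseless pure-decline cohort (plateau far below reach, so every latent
## trajectory is exactly linear in t and lead/lag interpolation is exact)
linear_cohort <- function(n = 12, seed = 6) {
  simulate_cohort(sim_config(
    n_patients = n, followup_days = 1080, min_followup_days = 1080,
    noise_sd = 0, visit_jitter_days = 0, skip_prob_base = 0,
    skip_prob_value_coef = 0, plateau_mean = -50, plateau_sd = 0,
    deep_response_prob = 0, clip_range = c(-60, 2), seed = seed))
}

complete_aligned <- function(n = 12, seed = 6) {
  co <- linear_cohort(n, seed)
  align_to_grid(co$measurements[, .(patient_id, day, std_value)])
}

test_that("a sweep leaves a complete grid unchanged", {
  al <- complete_aligned()
  sw <- impute_sweep(al)
  expect_identical(sw$grid$value, al$value)
  expect_false(any(sw$grid$was_imputed))
})

test_that("noiseless single missing cell is imputed deterministically at the linear predictor", {
  al <- complete_aligned(n = 15)
  hole <- copy(al)
  hole$value[hole$patient_id == "P0003" & hole$t_index == 4L] <- NA
  s1 <- impute_sweep(hole)
  set.seed(999)  # different RNG state must not matter when sigma ~ 0
  s2 <- impute_sweep(hole)
  v1 <- s1$grid[patient_id == "P0003" & t_index == 4L, value]
  expect_equal(v1, s2$grid[patient_id == "P0003" & t_index == 4L, value],
               tolerance = 1e-6)
  truth <- al[patient_id == "P0003" & t_index == 4L, value]
  expect_lt(abs(v1 - truth), 0.05)
})

test_that("multiple imputation preserves observed cells and completes the grid", {
  co <- shared_cohort()
  al <- cohort_aligned(co)
  imp <- run_multiple_imputation(al, co$covariates, burnin = 5, m = 4, seed = 31)
  obs_idx <- !is.na(al$value)
  key <- al[obs_idx, .(patient_id, t_index, value)]
  for (d in imp$datasets) {
    m <- d[key, on = c("patient_id", "t_index")]
    expect_identical(m$value, key$value)   # bitwise observed-cell preservation
    expect_false(anyNA(d$value))           # completeness inside follow-up
  }
  ## uncertainty propagated: the m datasets differ at imputed cells
  imp_cells <- sapply(imp$datasets, function(d) d[was_imputed == TRUE, value])
  expect_gt(max(apply(imp_cells, 1, sd)), 0)
})

test_that("burnin = 0, m = 1 on noiseless data is deterministic iterated linear prediction", {
  al <- complete_aligned(n = 15)
  hole <- copy(al)
  drop_cells <- hole[, .I[t_index %in% c(3L, 5L) & patient_id %in% c("P0002", "P0007")]]
  hole$value[drop_cells] <- NA
  i1 <- run_multiple_imputation(hole, burnin = 0, m = 1, seed = 1)
  i2 <- run_multiple_imputation(hole, burnin = 0, m = 1, seed = 2)
  expect_equal(i1$datasets[[1]]$value, i2$datasets[[1]]$value, tolerance = 1e-5)
})

test_that("between-imputation spread grows with residual noise", {
  spread <- function(noise) {
    co <- simulate_cohort(sim_config(n_patients = 60, noise_sd = noise, seed = 88))
    al <- align_to_grid(co$measurements[, .(patient_id, day, std_value)])
    imp <- run_multiple_imputation(al, burnin = 5, m = 5, seed = 12)
    draws <- sapply(imp$datasets, function(d) d[was_imputed == TRUE, value])
    mean(apply(draws, 1, sd))
  }
  expect_gt(spread(1.0), spread(0.2))
})

test_that("coefficient traces do not diverge and near neighbours dominate", {
  co <- shared_cohort()
  imp <- run_multiple_imputation(cohort_aligned(co), co$covariates,
                                 burnin = 15, m = 2, seed = 7)
  cs <- convergence_summary(imp, min_n = 40)
  ## no systematic upward drift across burn-in
  slope <- coef(lm(max_change_se ~ iteration, data = cs))[2]
  expect_lt(slope, 0.05)
  ## lag1/lead1 carry the strongest coefficients in the final fits
  tr <- imp$trace[iteration == max(iteration) & n_fit >= 40]
  med <- sapply(c("lag2", "lag1", "lead1", "lead2"), function(cn)
    median(abs(tr[coefficient == cn, estimate])))
  expect_gt(med["lag1"], med["lag2"])
  expect_gt(med["lag1"], med["lead2"])
  expect_gt(med["lead1"], med["lag2"])
  expect_gt(med["lead1"], med["lead2"])
})

test_that("mask_and_recover validates input and handles degenerate masks", {
  co <- shared_cohort()
  expect_error(mask_and_recover(co$true_grid, mask_fraction = 0), "mask_fraction")
  expect_error(mask_and_recover(co$true_grid, mask_fraction = 1), "mask_fraction")
  ## tiny grid, tiny fraction: empty mask reported as empty
  g <- dtab(patient_id = rep("P1", 4), t_index = 0:3, value = rnorm(4))
  r <- mask_and_recover(g, mask_fraction = 0.05, seed = 1)
  expect_equal(r$n_masked, 0L)
  expect_true(is.na(r$rmse))
})

test_that("noiseless data is recovered almost exactly", {
  co <- linear_cohort(n = 40, seed = 9)
  r <- mask_and_recover(co$true_grid, co$covariates, mask_fraction = 0.1,
                        seed = 2, burnin = 5, m = 3)
  expect_lt(r$rmse, 0.05)
})
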