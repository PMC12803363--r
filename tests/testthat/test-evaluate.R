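dtab <- data.table::data.table

mk_preds <- function(pred_by_imp, wvar = 0, id = "P1", t = 3L) {
  dtab(imputation_id = seq_along(pred_by_imp), learner = "xgboost",
       spec = "full", horizon = 1L, patient_id = id, t_index = t,
       prediction = pred_by_imp, within_variance = wvar,
       target = 0)
}

test_that("Rubin pooling matches hand-computed fixtures exactly", {
  ## identical predictions: B = 0, T = W
  p <- pool_predictions(mk_preds(rep(2.5, 4), wvar = 0.3))
  expect_equal(p$qbar, 2.5)
  expect_equal(p$B, 0)
  expect_equal(p$T_var, 0.3)
  expect_equal(p$df, Inf)
  ## m = 2, predictions {1, 3}, zero within variance:
  ## Qbar = 2, B = 2, T = (1 + 1/2) * 2 = 3
  p <- pool_predictions(mk_preds(c(1, 3), wvar = 0))
  expect_equal(p$qbar, 2)
  expect_equal(p$W, 0)
  expect_equal(p$B, 2)
  expect_equal(p$T_var, 3)
  ## df = (m-1)(1 + W/((1+1/m)B))^2 = 1 here; CI uses t_1
  expect_equal(p$df, 1)
  expect_equal(p$ci_high - p$ci_low, 2 * qt(0.975, 1) * sqrt(3))
  expect_true(p$ci_low <= p$qbar && p$qbar <= p$ci_high)
})

test_that("interval width grows with between-imputation variance at fixed W", {
  narrow <- pool_predictions(mk_preds(c(1.9, 2.0, 2.1), wvar = 0.2))
  wide <- pool_predictions(mk_preds(c(1.0, 2.0, 3.0), wvar = 0.2))
  expect_gt(wide$T_var, narrow$T_var)
  expect_gt(wide$ci_high - wide$ci_low, narrow$ci_high - narrow$ci_low)
})

test_that("mismatched coverage across imputations is rejected", {
  p <- rbind(mk_preds(c(1, 2)), mk_preds(3, id = "P2")[1])
  expect_error(pool_predictions(p), "coverage")
})

test_that("negative within variance is rejected", {
  expect_error(pool_predictions(mk_preds(c(1, 2), wvar = -1)), "within_variance")
})

test_that("RMSE matches hand computations and its invariances", {
  base <- dtab(imputation_id = 1L, learner = "rnn", spec = "full",
               horizon = 1L, patient_id = c("A", "B"), t_index = 3L,
               prediction = c(0, 0), within_variance = 0, target = c(3, 4))
  r <- compute_rmse(base)
  expect_equal(r$overall$rmse, sqrt(12.5), tolerance = 1e-12)
  ## duplicating rows leaves the RMSE unchanged
  r2 <- compute_rmse(rbind(base, base))
  expect_equal(r2$overall$rmse, r$overall$rmse)
  ## perfect predictions: RMSE 0 with no between-imputation contribution
  perfect <- copy(base)[, prediction := target]
  perfect <- rbind(perfect, copy(perfect)[, imputation_id := 2L])
  rp <- compute_rmse(perfect)
  expect_equal(rp$overall$rmse, 0)
  expect_equal(rp$overall$B, 0)
  expect_equal(rp$overall$se, 0)
})

rand_preds <- function(m = 4, n = 60, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(m), function(k)
    dtab(imputation_id = k, learner = "xgboost", spec = "full", horizon = 1L,
         patient_id = rep(sprintf("P%02d", 1:(n / 4)), each = 4),
         t_index = rep(2:5, n / 4),
         prediction = rnorm(n), within_variance = runif(n, 0, 0.1),
         target = rnorm(n))))
}

test_that("pooled RMSE lies within the per-imputation range and per-t cells aggregate", {
  p <- rand_preds()
  r <- compute_rmse(p, min_rows = 1)
  expect_gte(r$overall$rmse, min(r$per_imputation$rmse))
  expect_lte(r$overall$rmse, max(r$per_imputation$rmse))
  ## within one imputation, row-weighted per-t MSEs average to the overall MSE
  p1 <- p[imputation_id == 1]
  per_t <- p1[, .(mse = mean((prediction - target)^2), n = .N), by = t_index]
  expect_equal(sum(per_t$mse * per_t$n) / sum(per_t$n),
               r$per_imputation[imputation_id == 1, mse], tolerance = 1e-12)
})

test_that("sparse per-time cells are suppressed", {
  p <- rand_preds()
  r <- compute_rmse(p, min_rows = 10)
  expect_true(all(r$per_t$suppressed[r$per_t$n_rows < 10]))
  expect_true(all(is.na(r$per_t$rmse[r$per_t$suppressed])))
})

test_that("pooled SE decreases with more imputations (replicate average)", {
  ses <- sapply(1:6, function(s) {
    c(compute_rmse(rand_preds(m = 2, seed = s))$overall$se,
      compute_rmse(rand_preds(m = 10, seed = s))$overall$se)
  })
  expect_lt(mean(ses[2, ]), mean(ses[1, ]))
})

test_that("evaluation summary reports ratios and the four ordering flags", {
  p <- do.call(rbind, lapply(c("xgboost", "rnn"), function(lr)
    do.call(rbind, lapply(c("full", "skipped"), function(sp)
      do.call(rbind, lapply(1:2, function(h) {
        q <- rand_preds(m = 2, seed = h)
        q[, `:=`(learner = lr, spec = sp, horizon = h)]
      }))))))
  r <- compute_rmse(p)
  s <- evaluation_summary(r, target_sd = 2.83)
  expect_equal(nrow(s$table), 8L)
  expect_equal(s$table$ratio, s$table$rmse / 2.83)
  expect_equal(nrow(s$orderings), 8L)  # 2 learners x (2 horizons + 2 specs)
  ## unit ratio when RMSE equals the SD
  r1 <- compute_rmse(rand_preds())
  expect_equal(evaluation_summary(r1, r1$overall$rmse)$table$ratio, 1)
})
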