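dtab <- data.table::data.table

one_patient_grid <- function(values) {
  dtab(patient_id = "P1", t_index = seq_along(values) - 1L, value = values)
}

adh_table <- function(values, id = "P1") {
  dtab(patient_id = id, t_index = seq_along(values) - 1L, adherence = values)
}

covs1 <- dtab(patient_id = "P1", age_at_dx = 50, bmi = 28, sex = "M",
              first_line_treatment = "imatinib")

test_that("feature rows vanish when the grid is too short", {
  g <- one_patient_grid(c(0, -1, -2))            # t = 0, 1, 2
  f <- build_features(g, adh_table(c(1, 1, 1)), covs1, "full", horizon = 1)
  expect_equal(nrow(f), 0L)
})

test_that("a constant trajectory yields constant features and zero 6-month change", {
  g <- one_patient_grid(rep(-3, 6))
  a <- adh_table(rep(0.9, 6))
  f <- build_features(g, a, covs1, "full", horizon = 1)
  expect_true(all(f$y_t == -3 & f$y_lag1 == -3 & f$y_lag2 == -3 & f$target == -3))
  s <- build_features(g, a, covs1, "skipped", horizon = 1)
  expect_true(all(s$d6 == 0))
})

test_that("feature tables equal a hand-enumerated fixture", {
  v <- c(0.5, -1, -2.5, -3, -3.2, -3.1)
  a <- c(1, 0.8, 0.6, 1, 0.9, 0.7)
  g <- one_patient_grid(v)
  f <- build_features(g, adh_table(a), covs1, "full", horizon = 1)
  expect_equal(f$t_index, 2:4)
  expect_equal(f$y_t, v[3:5])
  expect_equal(f$y_lag1, v[2:4])
  expect_equal(f$y_lag2, v[1:3])
  expect_equal(f$adh_t, a[2:4])       # interval ending at the origin
  expect_equal(f$adh_lag1, a[1:3])
  expect_equal(f$time_since_dx, c(180, 270, 360))
  expect_equal(f$target, v[4:6])
  s <- build_features(g, adh_table(a), covs1, "skipped", horizon = 2)
  expect_equal(s$t_index, 2:3)
  expect_equal(s$d6, v[3:4] - v[1:2])
  expect_equal(s$target, v[5:6])
})

test_that("the skipped specification carries no function of the last visit", {
  g <- one_patient_grid(rnorm(8))
  s <- build_features(g, adh_table(rep(1, 8)), covs1, "skipped", horizon = 1)
  expect_false("y_lag1" %in% names(s))
  expect_setequal(setdiff(names(s), c("patient_id", "t_index", "target")),
                  c("y_t", "d6", "adh_t", "adh_lag1", "age_at_dx", "time_since_dx"))
})

test_that("rows lacking adherence are dropped and counted", {
  g <- one_patient_grid(rnorm(8))
  a <- adh_table(rep(0.5, 3))                    # indices 0..2 only
  f <- build_features(g, a, covs1, "full", horizon = 1)
  expect_true(all(f$t_index <= 3))
  expect_gt(attr(f, "n_dropped"), 0)
})

test_that("an incomplete grid is rejected", {
  g <- one_patient_grid(c(0, NA, -2, -3, -4, -5))
  expect_error(build_features(g, adh_table(rep(1, 6)), covs1, "full", 1),
               "imputation")
})

test_that("patient split is an exact, deterministic partition", {
  ids <- sprintf("P%02d", 1:10)
  s1 <- split_patients(ids, 0.8, seed = 5)
  expect_equal(sum(s1$role == "TRAIN"), 8L)
  expect_equal(sum(s1$role == "TEST"), 2L)
  expect_identical(s1, split_patients(ids, 0.8, seed = 5))
  expect_setequal(s1$patient_id, ids)
  expect_error(split_patients(ids[1:3], 0.8, 1), "at least 5")
})

test_that("both learners reproduce a constant target", {
  set.seed(10)
  n <- 80
  rows <- dtab(patient_id = rep(sprintf("P%02d", 1:20), each = 4),
               t_index = rep(2:5, 20),
               y_t = rnorm(n), y_lag1 = rnorm(n), y_lag2 = rnorm(n),
               adh_t = runif(n), adh_lag1 = runif(n),
               age_at_dx = runif(n, 30, 70),
               time_since_dx = rep(2:5, 20) * 90,
               target = 2.5)
  data.table::setattr(rows, "spec", "full")
  for (lrn in c("xgboost", "rnn")) {
    m <- train_learner(rows, lrn, small_hp[[lrn]], seed = 3)
    p <- predict(m, rows)
    tol <- if (lrn == "xgboost") 1e-8 else 0.1
    expect_lt(max(abs(p - 2.5)), tol)
  }
})

test_that("boosted trees nearly interpolate noiseless linear data", {
  set.seed(11)
  n_pat <- 200
  n <- n_pat * 10
  rows <- dtab(patient_id = rep(sprintf("P%04d", 1:n_pat), each = 10),
               t_index = rep(2:11, n_pat),
               y_t = rnorm(n, -4, 2), y_lag1 = rnorm(n, -4, 2),
               y_lag2 = rnorm(n, -4, 2),
               adh_t = runif(n), adh_lag1 = runif(n),
               age_at_dx = runif(n, 30, 70),
               time_since_dx = rep(2:11, n_pat) * 90)
  rows[, target := 1.5 * y_t - 2]
  data.table::setattr(rows, "spec", "full")
  test_ids <- sprintf("P%04d", (0.8 * n_pat + 1):n_pat)
  m <- train_learner(rows[!patient_id %in% test_ids], "xgboost",
                     list(nrounds = 1000L, eta = 0.3, max_depth = 5L,
                          min_node = 3L, patience = 60L), seed = 4)
  te <- rows[patient_id %in% test_ids]
  rmse <- sqrt(mean((predict(m, te) - te$target)^2))
  expect_lt(rmse, 0.1 * sd(rows$target))
})

test_that("prediction schema mismatches are rejected", {
  g <- one_patient_grid(rnorm(8))
  f <- build_features(g, adh_table(rep(1, 8)), covs1, "full", 1)
  s <- build_features(g, adh_table(rep(1, 8)), covs1, "skipped", 1)
  skip_if(nrow(f) < 3)
  m <- train_learner(f, "xgboost", list(nrounds = 5L), seed = 1)
  expect_error(predict(m, s), "schema mismatch")
})

test_that("within-imputation variance is nonnegative, zero for degenerate ensembles, and shrinks with n", {
  set.seed(12)
  mk_rows <- function(n_pat, const = FALSE) {
    n <- n_pat * 5L
    r <- dtab(patient_id = rep(sprintf("Q%03d", 1:n_pat), each = 5),
              t_index = rep(2:6, n_pat),
              y_t = rnorm(n), y_lag1 = rnorm(n), y_lag2 = rnorm(n),
              adh_t = runif(n), adh_lag1 = runif(n),
              age_at_dx = runif(n, 30, 70), time_since_dx = rep(2:6, n_pat) * 90)
    r[, target := if (const) 1 else y_t + rnorm(n, 0, 0.5)]
    data.table::setattr(r, "spec", "full")
    r
  }
  rows_c <- mk_rows(15, const = TRUE)
  mc <- train_learner(rows_c, "xgboost", list(nrounds = 20L), seed = 1)
  pc <- predict_with_uncertainty(mc, rows_c, B = 3, seed = 2)
  expect_true(all(pc$within_variance < 1e-12))   # identical sub-models
  small <- mk_rows(12); big <- mk_rows(120)
  ms <- train_learner(small, "xgboost", list(nrounds = 40L), seed = 1)
  mb <- train_learner(big, "xgboost", list(nrounds = 40L), seed = 1)
  ps <- predict_with_uncertainty(ms, small, B = 6, seed = 3)
  pb <- predict_with_uncertainty(mb, big, B = 6, seed = 3)
  expect_true(all(ps$within_variance >= 0))
  expect_lt(mean(pb$within_variance), mean(ps$within_variance))
})
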