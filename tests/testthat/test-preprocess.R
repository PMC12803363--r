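test_that("baseline selection prefers pre-treatment records, else earliest post-treatment", {
  expect_equal(select_baseline(c(-10, 5, 95), 0), -10)
  expect_equal(select_baseline(c(30, 120), 0), 30)
  expect_equal(select_baseline(42, 0), 42)
  expect_equal(select_baseline(c(-50, -3, 10), 0), -3)
  expect_error(select_baseline(numeric(0)), "empty")
})

test_that("standardization applies the log-ratio formula in the configured base", {
  mk <- function(raw, fmt = "A") data.table::data.table(
    patient_id = "P1", day = 0L, raw_value = raw, assay_format = fmt)
  med <- c(A = 100)
  expect_equal(standardize(mk(100), med)$std_value, 0)
  expect_equal(standardize(mk(10), med)$std_value, log(10 / 100),
               tolerance = 1e-12)
  expect_equal(standardize(mk(10), med)$std_value, -2.302585, tolerance = 1e-6)
  expect_equal(standardize(mk(100), c(A = 10), log_base = "base10")$std_value, 1)
  expect_error(standardize(mk(-1), med), "positive")
  expect_error(standardize(mk(10, "B"), med), "assay format")
})

test_that("standardization is invertible given the median table", {
  co <- shared_cohort()
  med <- format_median_table(co$measurements, co$treatment)
  std <- standardize(co$measurements, med, co$treatment)
  back <- unstandardize(std$std_value,
                        co$measurements$assay_format[match(
                          paste(std$patient_id, std$day),
                          paste(co$measurements$patient_id, co$measurements$day))],
                        med)
  expect_equal(unname(back), co$measurements$raw_value[match(
    paste(std$patient_id, std$day),
    paste(co$measurements$patient_id, co$measurements$day))],
    tolerance = 1e-10)
})

test_that("format medians are medians of baseline raws and thin formats warn", {
  meas <- data.table::data.table(
    patient_id = rep(c("P1", "P2", "P3"), each = 2),
    day = rep(c(0L, 90L), 3),
    raw_value = c(50, 5, 70, 7, 90, 9),
    assay_format = "A")
  tr <- data.table::data.table(patient_id = c("P1", "P2", "P3"),
                               treatment_start_day = 0L)
  med <- format_median_table(meas, tr)
  expect_equal(unname(med["A"]), 70)  # median of baselines 50, 70, 90
  meas$assay_format[1:2] <- "B"
  expect_warning(format_median_table(meas, tr), "baseline patients")
})

simple_grid <- function(days, values = seq_along(days)) {
  align_to_grid(data.table::data.table(
    patient_id = "P1", day = days, std_value = values, baseline_day = 0L))
}

test_that("alignment window and assignment rules match the stated examples", {
  g <- simple_grid(c(0L, 100L))
  expect_equal(g[t_index == 1, value], 2)       # day 100 -> t=1 (dist 10)
  g <- simple_grid(c(0L, 140L))
  expect_true(is.na(g[t_index == 1, value]))    # dist 50 to t=1 exceeds 45
  expect_equal(g[t_index == 2, value], 2)       # dist 40 to t=2
  g <- simple_grid(c(0L, 200L))                 # nothing in [45, 135]
  expect_true(is.na(g[t_index == 1, value]))
})

test_that("alignment ties go to the earlier observation / earlier grid index", {
  ## two observations equidistant from t=1 (days 80 and 100): earlier one wins
  g <- simple_grid(c(0L, 80L, 100L), values = c(9, 1, 2))
  expect_equal(g[t_index == 1, value], 1)
  ## one observation at exactly 45 days from both t=0 and t=1: earlier index
  g <- align_to_grid(data.table::data.table(
    patient_id = "P1", day = 45L, std_value = 7, baseline_day = 0L))
  expect_equal(g[t_index == 0, value], 7)
  expect_true(all(is.na(g[t_index > 0, value])))
})

test_that("alignment matches the brute-force oracle on random instances", {
  set.seed(404)
  for (rep in 1:300) {
    n_obs <- sample(1:8, 1)
    days <- sort(sample(0:600, n_obs))
    vals <- rnorm(n_obs)
    g <- align_to_grid(data.table::data.table(
      patient_id = "P1", day = days, std_value = vals, baseline_day = 0L))
    t_max <- max(g$t_index)
    expect_identical(g$value, oracle_align(days, vals, 90L, 45L, t_max))
  }
})

test_that("non-missing cells never exceed observations; +90-day shift advances indices by one", {
  set.seed(11)
  for (rep in 1:30) {
    days <- sort(sample(0:720, sample(2:10, 1)))
    vals <- rnorm(length(days))
    g1 <- align_to_grid(data.table::data.table(
      patient_id = "P1", day = days, std_value = vals, baseline_day = 0L))
    expect_lte(sum(!is.na(g1$value)), length(days))
    g2 <- align_to_grid(data.table::data.table(
      patient_id = "P1", day = days + 90L, std_value = vals, baseline_day = 0L))
    ## interior equivariance: cell t of g1 appears at t+1 in g2
    common <- 0:max(g1$t_index)
    expect_identical(g1[t_index %in% common, value],
                     g2[t_index %in% (common + 1L), value])
  }
})
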