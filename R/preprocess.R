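## Standardization and grid alignment ----------------------------------------

#' Select the baseline measurement day for one patient
#'
#' The baseline is the record closest to therapy initiation among
#' pre-treatment records (day <= `treatment_start_day`); when no pre-treatment
#' record exists, the earliest post-treatment record is used.
#'
#' @param days integer vector of measurement days (strictly increasing).
#' @param treatment_start_day day therapy began.
#' @return the selected baseline day.
#' @export
select_baseline <- function(days, treatment_start_day = 0L) {
  stop_if(length(days) == 0L, "empty measurement series")
  pre <- days[days <= treatment_start_day]
  if (length(pre)) pre[which.min(abs(pre - treatment_start_day))] else min(days)
}

#' Baseline median raw value per assay format
#'
#' For every patient, picks the baseline record via [select_baseline()] and
#' returns the median baseline raw value within each assay format.  Formats
#' whose baselines come from fewer than `min_patients` patients are kept but
#' flagged with a warning, since their median rests on thin support.
#'
#' @param measurements `data.table` with `patient_id`, `day`, `raw_value`,
#'   `assay_format`.
#' @param treatment `data.table` with `patient_id`, `treatment_start_day`.
#' @param min_patients warn when a format has fewer baselines than this.
#' @return named numeric vector of medians (one entry per format present).
#' @export
format_median_table <- function(measurements, treatment, min_patients = 3L) {
  m <- as.data.table(measurements)
  tr <- as.data.table(treatment)
  m <- tr[m, on = "patient_id"]
  m[is.na(treatment_start_day), treatment_start_day := 0L]
  base <- m[, {
    bd <- select_baseline(day, treatment_start_day[1])
    .SD[day == bd][1]
  }, by = patient_id]
  med <- base[, .(med = median(raw_value), n = .N), by = assay_format]
  thin <- med[n < min_patients, assay_format]
  if (length(thin))
    warning("format(s) with < ", min_patients, " baseline patients: ",
            paste(thin, collapse = ", "), call. = FALSE)
  stop_if(any(med$med <= 0), "non-positive format median")
  setNames(med$med, med$assay_format)
}

#' Standardize raw biomarker values
#'
#' Applies the log-ratio transform `std = log(raw / median_format)` in the
#' configured base, where `median_format` is the cohort median baseline value
#' for the record's assay format.  Also records each patient's baseline day,
#' which anchors the alignment grid.
#'
#' @param measurements `data.table` with `patient_id`, `day`, `raw_value`,
#'   `assay_format` (days strictly increasing within patient, raw values > 0).
#' @param medians named vector from [format_median_table()].
#' @param treatment `data.table` with `patient_id`, `treatment_start_day`;
#'   defaults to treatment at day 0 for everyone.
#' @param log_base `"natural"` (default) or `"base10"`.
#' @return `data.table` with `patient_id`, `day`, `std_value`, `baseline_day`.
#' @export
standardize <- function(measurements, medians, treatment = NULL,
                        log_base = c("natural", "base10")) {
  log_base <- match.arg(log_base)
  m <- as.data.table(measurements)
  stop_if(any(m$raw_value <= 0), "raw values must be positive (log transform)")
  unknown <- setdiff(unique(m$assay_format), names(medians))
  stop_if(length(unknown) > 0,
          paste("no median for assay format(s):", paste(unknown, collapse = ", ")))
  m[, {
    d <- diff(day)
    stop_if(any(d <= 0), "days must be strictly increasing within a patient")
  }, by = patient_id]
  if (is.null(treatment))
    treatment <- data.table(patient_id = unique(m$patient_id),
                            treatment_start_day = 0L)
  tr <- as.data.table(treatment)
  m <- tr[m, on = "patient_id"]
  m[is.na(treatment_start_day), treatment_start_day := 0L]
  denom <- if (log_base == "natural") 1 else log(10)
  out <- m[, .(patient_id, day,
               std_value = log(raw_value / medians[assay_format]) / denom)]
  bl <- m[, .(baseline_day = select_baseline(day, treatment_start_day[1])),
          by = patient_id]
  out <- bl[out, on = "patient_id"]
  setcolorder(out, c("patient_id", "day", "std_value", "baseline_day"))
  out[]
}

#' Invert the standardization
#'
#' @param std_value standardized values.
#' @param assay_format format label per value.
#' @param medians named median vector.
#' @param log_base as in [standardize()].
#' @return raw assay values.
#' @export
unstandardize <- function(std_value, assay_format, medians,
                          log_base = c("natural", "base10")) {
  log_base <- match.arg(log_base)
  base <- if (log_base == "natural") exp(1) else 10
  medians[assay_format] * base^std_value
}

## Greedy one-patient alignment: candidate (grid point, observation) pairs
## within the window, assigned by ascending distance; ties broken by earlier
## observation day, then earlier grid index; each side used at most once.
align_one <- function(rel_days, values, days, grid_days, window, t_max) {
  tt <- 0:t_max
  cand <- CJ(t = tt, j = seq_along(rel_days))
  cand[, dist := abs(rel_days[j] - grid_days * t)]
  cand <- cand[dist <= window]
  setorder(cand, dist, j, t)
  used_t <- logical(t_max + 1L)
  used_j <- logical(length(rel_days))
  val <- rep(NA_real_, t_max + 1L)
  mday <- rep(NA_integer_, t_max + 1L)
  for (k in seq_len(nrow(cand))) {
    t <- cand$t[k]; j <- cand$j[k]
    if (used_t[t + 1L] || used_j[j]) next
    used_t[t + 1L] <- TRUE; used_j[j] <- TRUE
    val[t + 1L] <- values[j]
    mday[t + 1L] <- days[j]
  }
  data.table(t_index = tt, value = val, matched_day = mday)
}

#' Align standardized series to a regular grid
#'
#' Constructs expected collection dates at `grid_days` intervals from each
#' patient's baseline day and pairs every grid point with the nearest
#' observation within `match_window_days` (closed window, integer days).
#' Each observation serves at most one grid point: pairs are assigned
#' greedily by ascending distance, ties broken by earlier observation then
#' earlier grid index.  Grid points left unpaired are missing (`NA`).  The
#' grid extends to the last index whose date is within the window of the
#' final observation.
#'
#' @param std output of [standardize()] (or any table with `patient_id`,
#'   `day`, `std_value`, optional `baseline_day` defaulting to 0).
#' @param grid_days grid spacing in days (default 90).
#' @param match_window_days half-width of the closed matching window
#'   (default 45).
#' @return `aligned_grid`: a `data.table` with `patient_id`, `t_index`,
#'   `value` (`NA` = missing) and `matched_day` (original day scale).
#' @export
align_to_grid <- function(std, grid_days = 90L, match_window_days = 45L) {
  s <- as.data.table(std)
  if (!"baseline_day" %in% names(s)) s[, baseline_day := 0L]
  stop_if(grid_days <= 0 || match_window_days < 0, "invalid grid parameters")
  out <- s[order(day), {
    rel <- day - baseline_day[1]
    t_max <- max(0L, as.integer((max(rel) + match_window_days) %/% grid_days))
    align_one(rel, std_value, day, grid_days, match_window_days, t_max)
  }, by = patient_id]
  setattr(out, "grid_days", as.integer(grid_days))
  setattr(out, "class", c("aligned_grid", class(out)))
  out[]
}
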