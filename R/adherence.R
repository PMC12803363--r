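## CMA9 adherence trajectories ------------------------------------------------

## Supply intervals with carry-over: each fill starts covering at
## max(fill_day, exhaustion of prior supply); returns matrix of [start, end)
## coverage intervals, truncated at observation_end.
supply_intervals <- function(fill_day, days_supplied, observation_end) {
  n <- length(fill_day)
  start <- end <- numeric(n)
  avail <- 0
  for (k in seq_len(n)) {
    start[k] <- max(fill_day[k], avail)
    end[k] <- start[k] + days_supplied[k]
    avail <- end[k]
  }
  end <- pmin(end, observation_end)
  keep <- end > start
  cbind(start = start[keep], end = end[keep])
}

#' Interval adherence by the CMA9 availability metric
#'
#' Computes, for each `grid_days`-day interval `[g*t, g*(t+1))` anchored at
#' day 0, the fraction of days covered by dispensed supply.  Supply carries
#' over: a fill collected while prior supply remains starts covering when
#' that supply is exhausted, so days are never double counted; oversupply
#' beyond `observation_end` is discarded.  Values are capped at 1 and
#' intervals before the first fill score 0.
#'
#' @param dispensations `data.table`/data.frame with `fill_day`,
#'   `days_supplied` (sorted by `fill_day`, positive supplies).  May be empty.
#' @param observation_end end of the observation window in days; defaults to
#'   the end of the interval containing the last covered day.
#' @param grid_days interval length in days (default 90).
#' @return `data.table` with `t_index` and `adherence` in `[0, 1]`, one row
#'   per interval from 0 through the last interval before `observation_end`.
#' @export
compute_cma9 <- function(dispensations, observation_end = NULL, grid_days = 90L) {
  d <- as.data.table(dispensations)
  stop_if(nrow(d) > 0 && any(d$days_supplied <= 0), "days_supplied must be positive")
  stop_if(nrow(d) > 1 && is.unsorted(d$fill_day), "dispensations must be sorted by fill_day")
  if (is.null(observation_end)) {
    observation_end <- if (nrow(d) == 0) grid_days else
      ceiling(max(d$fill_day + cumsum_supply_end(d)) / grid_days) * grid_days
  }
  stop_if(observation_end <= 0, "observation_end must be positive")
  n_int <- as.integer(ceiling(observation_end / grid_days))
  covered <- numeric(n_int)
  if (nrow(d) > 0) {
    iv <- supply_intervals(d$fill_day, d$days_supplied, observation_end)
    for (k in seq_len(nrow(iv))) {
      lo <- iv[k, "start"]; hi <- iv[k, "end"]
      t0 <- max(0L, as.integer(lo %/% grid_days))
      t1 <- min(n_int - 1L, as.integer((hi - 1e-9) %/% grid_days))
      for (t in t0:t1) {
        covered[t + 1L] <- covered[t + 1L] +
          max(0, min(hi, (t + 1) * grid_days) - max(lo, t * grid_days))
      }
    }
  }
  data.table(t_index = 0:(n_int - 1L),
             adherence = pmin(covered / grid_days, 1))
}

## crude upper bound for the default observation end
cumsum_supply_end <- function(d) sum(d$days_supplied)

#' Adherence trajectories for a cohort
#'
#' Applies [compute_cma9()] per patient.
#'
#' @param dispensations table with `patient_id`, `fill_day`, `days_supplied`.
#' @param observation_end single day or named vector (per patient).
#' @param grid_days interval length in days.
#' @return `data.table` with `patient_id`, `t_index`, `adherence`.
#' @export
compute_adherence <- function(dispensations, observation_end, grid_days = 90L) {
  d <- as.data.table(dispensations)
  ends <- observation_end
  d[order(fill_day), {
    oe <- if (length(ends) == 1L && is.null(names(ends))) ends else ends[[patient_id[1]]]
    compute_cma9(.SD, observation_end = oe, grid_days = grid_days)
  }, by = patient_id]
}
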