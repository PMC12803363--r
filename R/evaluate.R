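## Rubin's-rules pooling and accuracy reporting -------------------------------

## Core Rubin combination of m estimates q with within-variances w:
##   Qbar = mean(q); W = mean(w); B = var(q); T = W + (1 + 1/m) B
##   df = (m - 1) (1 + W / ((1 + 1/m) B))^2   (Inf when B = 0)
rubin_combine <- function(q, w) {
  m <- length(q)
  qbar <- mean(q)
  W <- mean(w)
  B <- if (m > 1L) var(q) else 0
  T_var <- W + (1 + 1 / m) * B
  df <- if (B > 0 && m > 1L) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  list(qbar = qbar, W = W, B = B, T_var = T_var, df = df, m = m)
}

rubin_ci <- function(qbar, T_var, df, level = 0.95) {
  crit <- if (is.infinite(df) || df > 100) qnorm(1 - (1 - level) / 2)
  else qt(1 - (1 - level) / 2, df)
  c(qbar - crit * sqrt(T_var), qbar + crit * sqrt(T_var))
}

#' Pool per-imputation predictions with Rubin's rules
#'
#' Consolidates one prediction per imputed dataset into a pooled point
#' prediction with within- (`W`), between- (`B`) and total (`T_var`)
#' variance, Rubin degrees of freedom, and a 95% interval (Student-t with
#' Rubin df; normal when df > 100).
#'
#' @param predictions long table with `imputation_id`, `learner`, `spec`,
#'   `horizon`, `patient_id`, `t_index`, `prediction`, `within_variance`.
#' @param level confidence level (default 0.95).
#' @return `data.table` keyed by (`learner`, `spec`, `horizon`,
#'   `patient_id`, `t_index`) with `qbar`, `W`, `B`, `T_var`, `df`,
#'   `ci_low`, `ci_high`.
#' @export
pool_predictions <- function(predictions, level = 0.95) {
  p <- as.data.table(predictions)
  stop_if(any(p$within_variance < 0), "negative within_variance")
  m <- length(unique(p$imputation_id))
  counts <- p[, .N, by = .(learner, spec, horizon, patient_id, t_index)]
  stop_if(any(counts$N != m),
          "mismatched (patient, t) coverage across imputations")
  out <- p[, {
    rc <- rubin_combine(prediction, within_variance)
    ci <- rubin_ci(rc$qbar, rc$T_var, rc$df, level)
    .(qbar = rc$qbar, W = rc$W, B = rc$B, T_var = rc$T_var, df = rc$df,
      ci_low = ci[1], ci_high = ci[2])
  }, by = .(learner, spec, horizon, patient_id, t_index)]
  out[]
}

## delta-method within-variance of an RMSE inside one imputation:
## Var(RMSE) ~= Var(e^2) / (4 n MSE); 0 when the fit is exact.
rmse_within_var <- function(sq_err) {
  n <- length(sq_err)
  mse <- mean(sq_err)
  if (mse <= 0 || n < 2L) return(0)
  var(sq_err) / (4 * n * mse)
}

#' Pooled RMSE report across imputations
#'
#' Within each imputed dataset the RMSE of predictions against that
#' dataset's targets is computed (overall and per grid index); the `m`
#' per-imputation RMSEs are then pooled with Rubin's rules, with the
#' within-imputation variance of an RMSE obtained by the delta method
#' `Var(RMSE) = Var(e^2) / (4 n MSE)`.  Per-index cells backed by fewer
#' than `min_rows` test rows are suppressed (flagged, value `NA`).
#'
#' @param predictions long table with `imputation_id`, `learner`, `spec`,
#'   `horizon`, `t_index`, `prediction`, `target`.
#' @param min_rows per-index suppression threshold (default 10).
#' @return object of class `rmse_report`: list with `overall`, `per_t` and
#'   `per_imputation` tables.
#' @export
compute_rmse <- function(predictions, min_rows = 10L) {
  p <- as.data.table(predictions)
  stop_if(nrow(p) == 0L, "empty prediction set")
  stop_if(!all(c("prediction", "target", "imputation_id") %in% names(p)),
          "predictions must carry imputation_id, prediction and target")
  per_imp <- p[, {
    e2 <- (prediction - target)^2
    .(mse = mean(e2), rmse = sqrt(mean(e2)), wvar = rmse_within_var(e2),
      n_rows = .N)
  }, by = .(learner, spec, horizon, imputation_id)]
  overall <- per_imp[, {
    rc <- rubin_combine(rmse, wvar)
    .(rmse = rc$qbar, se = sqrt(rc$T_var), W = rc$W, B = rc$B, df = rc$df,
      m = rc$m, n_rows = n_rows[1])
  }, by = .(learner, spec, horizon)]
  per_t_imp <- p[, {
    e2 <- (prediction - target)^2
    .(rmse = sqrt(mean(e2)), wvar = rmse_within_var(e2), n_rows = .N)
  }, by = .(learner, spec, horizon, t_index, imputation_id)]
  per_t <- per_t_imp[, {
    rc <- rubin_combine(rmse, wvar)
    supp <- n_rows[1] < min_rows
    .(rmse = if (supp) NA_real_ else rc$qbar,
      se = if (supp) NA_real_ else sqrt(rc$T_var),
      n_rows = n_rows[1], suppressed = supp)
  }, by = .(learner, spec, horizon, t_index)]
  structure(list(overall = overall[], per_t = per_t[],
                 per_imputation = per_imp[]),
            class = "rmse_report")
}

#' @export
print.rmse_report <- function(x, ...) {
  cat("Pooled RMSE (Rubin's rules across imputations)\n")
  print(x$overall)
  invisible(x)
}

#' Accuracy summary relative to the outcome's marginal variability
#'
#' Adds RMSE / SD ratios and the two directional orderings of interest:
#' full-information vs skipped-last-visit at each horizon, and horizon 1 vs
#' horizon 2 within each specification.
#'
#' @param report a [compute_rmse()] result.
#' @param target_sd marginal SD of the (standardized) outcome.
#' @return list with `table` (overall RMSEs plus `ratio`) and `orderings`
#'   (`learner`, `comparison`, `holds`).
#' @export
evaluation_summary <- function(report, target_sd) {
  stop_if(!inherits(report, "rmse_report"), "report must be an rmse_report")
  tab <- copy(report$overall)
  tab[, ratio := rmse / target_sd]
  ords <- list()
  for (lr in unique(tab$learner)) {
    sub <- tab[learner == lr]
    for (h in sort(unique(sub$horizon))) {
      f <- sub[spec == "full" & horizon == h, rmse]
      s <- sub[spec == "skipped" & horizon == h, rmse]
      if (length(f) && length(s))
        ords[[length(ords) + 1L]] <- data.table(
          learner = lr, comparison = sprintf("full<=skipped@h%d", h),
          holds = f <= s)
    }
    for (sp in unique(sub$spec)) {
      h1 <- sub[spec == sp & horizon == 1L, rmse]
      h2 <- sub[spec == sp & horizon == 2L, rmse]
      if (length(h1) && length(h2))
        ords[[length(ords) + 1L]] <- data.table(
          learner = lr, comparison = sprintf("h1<=h2@%s", sp),
          holds = h1 <= h2)
    }
  }
  list(table = tab[], orderings = rbindlist(ords))
}
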