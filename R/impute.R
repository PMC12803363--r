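## Local windowed multiple imputation -----------------------------------------
##
## Missing grid cells are filled one time index at a time.  At index t an
## interval-specific linear model
##     Y_t = alpha_t + beta_t . Z_t + gamma_t . X + eps,   eps ~ N(0, sigma_t^2)
## is fit by OLS on patients observed at t, where Z_t holds the two lagged and
## two lead grid values (de-meaned by frozen per-column cohort means; entries
## unavailable at series boundaries or still missing contribute 0, i.e. the
## column mean) and X holds baseline covariates.  Missing cells are redrawn
## from the fitted model plus a Gaussian residual draw; sweeps proceed in
## ascending t, Gibbs-style, and are repeated through a burn-in phase before m
## completed datasets are drawn.

WINDOW_NAMES <- c("lag2", "lag1", "lead1", "lead2")

#' Build the baseline-covariate design matrix
#'
#' One-hot encodes `sex` (reference `"F"`) and `first_line_treatment`
#' (reference `"imatinib"`); missing BMI is replaced by the cohort mean with
#' a missingness indicator column added.
#'
#' @param covariates table with `patient_id`, `age_at_dx`, `bmi`, `sex`,
#'   `first_line_treatment`; or `NULL` for a zero-column matrix.
#' @param ids patient ids giving the row order.
#' @return numeric matrix with one row per id.
#' @export
covariate_design <- function(covariates, ids) {
  if (is.null(covariates))
    return(matrix(numeric(0), nrow = length(ids), ncol = 0,
                  dimnames = list(ids, NULL)))
  cv <- as.data.table(covariates)
  cv <- cv[match(ids, patient_id)]
  stop_if(anyNA(cv$patient_id), "covariates missing for some patients")
  bmi <- cv$bmi
  bmi_miss <- as.numeric(is.na(bmi))
  if (any(bmi_miss > 0)) bmi[is.na(bmi)] <- mean(bmi, na.rm = TRUE)
  X <- cbind(age_at_dx = cv$age_at_dx,
             bmi = bmi,
             sex_M = as.numeric(cv$sex == "M"),
             treat_dasatinib = as.numeric(cv$first_line_treatment == "dasatinib"),
             treat_nilotinib = as.numeric(cv$first_line_treatment == "nilotinib"))
  if (any(bmi_miss > 0)) X <- cbind(X, bmi_missing = bmi_miss)
  rownames(X) <- ids
  X
}

#' Fit the interval-specific local linear model
#'
#' Ordinary least squares of the observed values at one grid index on the
#' de-meaned lead/lag window and baseline covariates.  The residual SD uses
#' denominator `n - rank` (equal to `n - p - 1` for a full-rank design with
#' `p` predictors).  The fit is flagged degenerate when fewer rows than
#' parameters plus one are available; rank-deficient designs keep the fit
#' with aliased coefficients set to zero.
#'
#' @param y observed responses at the target index.
#' @param Z numeric matrix of window predictors (columns `lag2`, `lag1`,
#'   `lead1`, `lead2`), already de-meaned; missing entries must already be 0.
#' @param X optional covariate matrix from [covariate_design()].
#' @param t_index grid index the fit belongs to (metadata).
#' @return object of class `local_fit`: list with `coef` (named, intercept
#'   first), `se`, `sigma`, `n_fit`, `rank`, `degenerate`, `t_index`.
#' @export
fit_local_model <- function(y, Z, X = NULL, t_index = NA_integer_) {
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- WINDOW_NAMES[seq_len(ncol(Z))]
  D <- cbind(`(Intercept)` = 1, Z)
  if (!is.null(X) && ncol(as.matrix(X)) > 0) D <- cbind(D, as.matrix(X))
  n <- length(y)
  p <- ncol(D)
  if (n < p + 1L) {
    return(structure(list(coef = setNames(rep(0, p), colnames(D)),
                          se = setNames(rep(NA_real_, p), colnames(D)),
                          sigma = NA_real_, n_fit = n, rank = 0L,
                          degenerate = TRUE, t_index = t_index),
                     class = "local_fit"))
  }
  fit <- lm.fit(D, y)
  cf <- fit$coefficients
  aliased <- is.na(cf)
  cf[aliased] <- 0
  rank <- fit$rank
  res <- fit$residuals
  dfree <- max(n - rank, 1L)
  s2 <- sum(res^2) / dfree
  ## standard errors from the (pivoted) R factor
  se <- rep(NA_real_, p)
  names(se) <- names(cf)
  if (rank > 0) {
    R <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
    R[lower.tri(R)] <- 0
    XtXinv <- chol2inv(R)
    piv <- fit$qr$pivot[seq_len(rank)]
    se[piv] <- sqrt(pmax(diag(XtXinv), 0) * s2)
  }
  structure(list(coef = cf, se = se, sigma = sqrt(s2), n_fit = n, rank = rank,
                 degenerate = FALSE, t_index = t_index),
            class = "local_fit")
}

#' @export
print.local_fit <- function(x, ...) {
  cat(sprintf("Local model at t = %s (n = %d%s): sigma = %.4g\n",
              x$t_index, x$n_fit, if (x$degenerate) ", DEGENERATE" else "",
              x$sigma))
  print(round(x$coef, 4))
  invisible(x)
}

## linear predictor for a matrix of window rows / covariate rows
linear_predictor <- function(fit, Z, X = NULL) {
  Z <- as.matrix(Z)
  Z[is.na(Z)] <- 0                       # missing predictor = de-meaned mean
  eta <- unname(fit$coef[1]) + drop(Z %*% fit$coef[1 + seq_len(ncol(Z))])
  if (!is.null(X) && ncol(as.matrix(X)) > 0) {
    X <- as.matrix(X)
    eta <- eta + drop(X %*% fit$coef[(2 + ncol(Z)):length(fit$coef)])
  }
  eta
}

#' Impute a single grid cell
#'
#' Returns the local-model linear predictor plus a Gaussian residual draw
#' with SD equal to the fitted residual SD.  Missing window entries are
#' treated as 0, i.e. the de-meaned column mean.  Uses the current R RNG
#' stream; seed with `set.seed()` for reproducibility.
#'
#' @param fit a non-degenerate [fit_local_model()] result.
#' @param window numeric vector of de-meaned window values (`NA` allowed).
#' @param covars optional covariate row (same columns as fit).
#' @return a single imputed standardized value.
#' @export
impute_cell <- function(fit, window, covars = NULL) {
  stop_if(fit$degenerate, "cannot impute from a degenerate fit")
  Z <- matrix(window, nrow = 1L)
  X <- if (is.null(covars)) NULL else matrix(covars, nrow = 1L)
  linear_predictor(fit, Z, X) + rnorm(1L, 0, fit$sigma)
}

## ---------------------------------------------------------------------------
## cohort-level engine

## Build matrices from an aligned grid (long) + covariates.
grid_state <- function(aligned, covariates = NULL) {
  a <- as.data.table(aligned)
  stop_if(anyDuplicated(a[, .(patient_id, t_index)]) > 0,
          "duplicate (patient, t_index) rows in aligned grid")
  ids <- unique(a$patient_id)
  Tmax <- max(a$t_index)
  Y <- obs <- inwin <- matrix(NA_real_, length(ids), Tmax + 1L,
                              dimnames = list(ids, NULL))
  idx <- cbind(match(a$patient_id, ids), a$t_index + 1L)
  Y[idx] <- a$value
  present <- matrix(FALSE, length(ids), Tmax + 1L, dimnames = list(ids, NULL))
  present[idx] <- TRUE                  # cell belongs to this patient's grid
  obsm <- !is.na(Y)
  ## follow-up window: first..last observed index per patient
  scope <- matrix(FALSE, length(ids), Tmax + 1L)
  for (r in seq_along(ids)) {
    w <- which(obsm[r, ])
    if (length(w)) {
      rng <- w[1]:w[length(w)]
      scope[r, rng] <- present[r, rng] & !obsm[r, rng]
    }
  }
  mu <- vapply(seq_len(Tmax + 1L), function(t) {
    v <- Y[obsm[, t], t]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  list(ids = ids, Y = Y, obs = obsm, present = present, scope = scope,
       mu = mu, X = covariate_design(covariates, ids), Tmax = Tmax)
}

## de-meaned lead/lag window matrix for target index t (0-based)
window_matrix <- function(Y, mu, t) {
  n <- nrow(Y)
  Tn <- ncol(Y)
  col <- function(tt) {
    if (tt < 0 || tt > Tn - 1L) return(rep(0, n))
    v <- Y[, tt + 1L] - mu[tt + 1L]
    v[is.na(v)] <- 0
    v
  }
  m <- cbind(lag2 = col(t - 2L), lag1 = col(t - 1L),
             lead1 = col(t + 1L), lead2 = col(t + 2L))
  m
}

nearest_fit <- function(fits, t) {
  ok <- which(vapply(fits, function(f) !is.null(f) && !f$degenerate, logical(1)))
  if (!length(ok)) return(NULL)
  fits[[ok[which.min(abs(ok - (t + 1L)))]]]
}

## One ascending-t sweep.  Fits at each index on originally observed rows
## with predictors from the current completed state; redraws every in-scope
## cell.  Degenerate indices borrow the nearest usable fit (from this sweep's
## earlier indices or a pre-pass on the entering state); with no usable fit
## anywhere the cell keeps its current (mean-initialized) value.
impute_sweep_state <- function(state, pmm = FALSE, pmm_k = 5L) {
  Y <- state$Y
  fits <- vector("list", state$Tmax + 1L)
  prepass <- vector("list", state$Tmax + 1L)
  for (t in 0:state$Tmax) {
    ridx <- which(state$obs[, t + 1L])
    if (length(ridx)) {
      Zt <- window_matrix(Y, state$mu, t)
      prepass[[t + 1L]] <- fit_local_model(Y[ridx, t + 1L],
                                           Zt[ridx, , drop = FALSE],
                                           state$X[ridx, , drop = FALSE],
                                           t_index = t)
    }
  }
  for (t in 0:state$Tmax) {
    Zt <- window_matrix(Y, state$mu, t)
    ridx <- which(state$obs[, t + 1L])
    fit <- if (length(ridx))
      fit_local_model(Y[ridx, t + 1L], Zt[ridx, , drop = FALSE],
                      state$X[ridx, , drop = FALSE], t_index = t)
    else NULL
    fits[[t + 1L]] <- fit
    use <- fit
    if (is.null(use) || use$degenerate) {
      use <- nearest_fit(fits, t) %||% nearest_fit(prepass, t)
    }
    targets <- which(state$scope[, t + 1L])
    if (!length(targets)) next
    if (is.null(use)) next               # no usable fit anywhere: keep value
    eta <- linear_predictor(use, Zt[targets, , drop = FALSE],
                            state$X[targets, , drop = FALSE])
    if (pmm && length(ridx)) {
      donors <- Y[ridx, t + 1L]
      donor_eta <- linear_predictor(use, Zt[ridx, , drop = FALSE],
                                    state$X[ridx, , drop = FALSE])
      k <- min(pmm_k, length(donors))
      Y[cbind(targets, t + 1L)] <- vapply(eta, function(e) {
        nb <- order(abs(donor_eta - e))[seq_len(k)]
        donors[sample(nb, 1L)]
      }, numeric(1))
    } else {
      Y[cbind(targets, t + 1L)] <- eta + rnorm(length(targets), 0, use$sigma)
    }
  }
  list(Y = Y, fits = fits)
}

#' One imputation sweep over an aligned cohort grid
#'
#' Iterates grid indices in ascending order; at each index refits the local
#' model on originally observed rows (predictors taken from the current
#' completed state) and redraws every originally missing cell inside the
#' patients' follow-up windows.  Observed cells are never modified.  Cells
#' still missing on entry are initialized at the frozen column means.
#'
#' @param aligned an [align_to_grid()] result (long, `NA` = missing).
#' @param covariates optional baseline covariate table.
#' @param pmm,pmm_k use predictive-mean-matching draws (nearest `pmm_k`
#'   observed donors by linear predictor) instead of Gaussian residual draws.
#' @return list with `grid` (completed long `data.table` adding
#'   `was_imputed`) and `fits` (per-index `local_fit`s).
#' @export
impute_sweep <- function(aligned, covariates = NULL, pmm = FALSE, pmm_k = 5L) {
  state <- grid_state(aligned, covariates)
  state$Y[state$scope] <- matrix(rep(state$mu, each = nrow(state$Y)),
                                 nrow(state$Y))[state$scope]
  res <- impute_sweep_state(state, pmm = pmm, pmm_k = pmm_k)
  list(grid = state_to_long(state, res$Y), fits = res$fits)
}

state_to_long <- function(state, Y) {
  dt <- data.table(
    patient_id = rep(state$ids, ncol(Y)),
    t_index = rep(0:state$Tmax, each = nrow(Y)),
    value = as.vector(Y),
    was_imputed = as.vector(state$scope))
  keep <- as.vector(state$present)
  dt <- dt[keep]
  setorder(dt, patient_id, t_index)
  dt[]
}

#' Local windowed multiple imputation
#'
#' Runs the full algorithm: mean initialization of missing cells, `burnin`
#' Gibbs-style sweeps (ascending grid index, refitting each interval model on
#' the current state), then `m` completed datasets, each obtained by one
#' additional sweep from the burned-in state under an independent random
#' stream.  Per-iteration coefficient traces are recorded for convergence
#' diagnostics.
#'
#' @param aligned an [align_to_grid()] result.
#' @param covariates optional covariate table (see [covariate_design()]).
#' @param burnin number of burn-in sweeps (default 15).
#' @param m number of completed datasets (default 10).
#' @param seed master integer seed.
#' @param pmm,pmm_k optional predictive-mean-matching draws.
#' @param independent_chains if `TRUE`, each of the `m` datasets is produced
#'   by its own full burn-in chain instead of sharing one burned-in state.
#' @return object of class `imputed_mi`: list with `datasets` (list of `m`
#'   completed long grids from [impute_sweep()]'s `grid` format), `trace`
#'   (`iteration`, `t_index`, `coefficient`, `estimate`, `se`, `n_fit`),
#'   `mu`, `burnin`, `m`, `seed`.
#' @export
run_multiple_imputation <- function(aligned, covariates = NULL, burnin = 15L,
                                    m = 10L, seed = 1L, pmm = FALSE,
                                    pmm_k = 5L, independent_chains = FALSE) {
  stop_if(burnin < 0 || m < 1, "burnin must be >= 0 and m >= 1")
  state <- grid_state(aligned, covariates)
  init <- function(st) {
    st$Y[st$scope] <- matrix(rep(st$mu, each = nrow(st$Y)), nrow(st$Y))[st$scope]
    st
  }
  trace <- list()
  run_chain <- function(st, seed_offset, record = FALSE) {
    for (it in seq_len(burnin)) {
      set.seed(derive_seed(seed, seed_offset + it))
      res <- impute_sweep_state(st, pmm = pmm, pmm_k = pmm_k)
      st$Y <- res$Y
      if (record) trace[[it]] <<- fits_to_trace(res$fits, it)
    }
    st
  }
  datasets <- vector("list", m)
  if (independent_chains) {
    for (k in seq_len(m)) {
      st <- run_chain(init(state), seed_offset = 10000L * k, record = (k == 1L))
      set.seed(derive_seed(seed, 10000L * k + 999L))
      datasets[[k]] <- impute_sweep_state(st, pmm, pmm_k)$Y
    }
  } else {
    st <- run_chain(init(state), seed_offset = 0L, record = TRUE)
    if (burnin == 0L) st <- init(state)
    for (k in seq_len(m)) {
      set.seed(derive_seed(seed, 5000L + k))
      datasets[[k]] <- impute_sweep_state(st, pmm, pmm_k)$Y
    }
  }
  structure(list(
    datasets = lapply(datasets, function(Y) state_to_long(state, Y)),
    trace = rbindlist(trace), mu = state$mu, burnin = as.integer(burnin),
    m = as.integer(m), seed = as.integer(seed)),
    class = "imputed_mi")
}

fits_to_trace <- function(fits, iteration) {
  rbindlist(lapply(fits, function(f) {
    if (is.null(f)) return(NULL)
    data.table(iteration = iteration, t_index = f$t_index,
               coefficient = names(f$coef), estimate = unname(f$coef),
               se = unname(f$se), n_fit = f$n_fit)
  }))
}

#' @export
print.imputed_mi <- function(x, ...) {
  n_imp <- sum(x$datasets[[1]]$was_imputed)
  cat(sprintf("Multiply imputed grids: m = %d, burn-in = %d, %d imputed cells per dataset\n",
              x$m, x$burnin, n_imp))
  invisible(x)
}

#' Combined long view of the imputed datasets
#'
#' @param imp an `imputed_mi` object.
#' @return `data.table` with `imputation_id`, `patient_id`, `t_index`,
#'   `value`, `was_imputed`.
#' @export
imputed_long <- function(imp) {
  rbindlist(lapply(seq_along(imp$datasets), function(k)
    cbind(imputation_id = k, imp$datasets[[k]])))
}

#' Burn-in convergence summary
#'
#' Change in the intercept and window coefficients between successive burn-in
#' iterations, over grid indices whose fits used at least `min_n` rows
#' (poorly populated tail indices are excluded, as in the per-interval
#' reporting guard).  Two summaries are returned per iteration: the maximum
#' absolute change, and the maximum change normalized by \eqn{\sqrt{2}}
#' times the coefficient's standard error — at stochastic equilibrium two
#' successive refits differ by about \eqn{\sqrt{2}\,\mathrm{SE}} of pure
#' resampling noise, so normalized values are roughly standard-normal draws
#' once the chain has stabilized, while systematic drift shows up as values
#' far above the max-of-normals range (the package treats values below 6 as
#' stabilized; see `tol_se` in the return attributes).
#'
#' @param imp an `imputed_mi` object with a recorded trace.
#' @param min_n minimum rows behind a fit for it to enter the summary.
#' @param tol_se stabilization threshold on the normalized change.
#' @return `data.table` with `iteration` (2..burnin), `max_abs_change` and
#'   `max_change_se`; attribute `tol_se` carries the threshold.
#' @export
convergence_summary <- function(imp, min_n = 50L, tol_se = 6) {
  tr <- imp$trace[coefficient %in% c("(Intercept)", WINDOW_NAMES) & n_fit >= min_n]
  stop_if(nrow(tr) == 0, "no trace recorded (burnin = 0 or min_n too high)")
  wide <- dcast(tr, t_index + coefficient ~ iteration, value.var = "estimate")
  wse <- dcast(tr, t_index + coefficient ~ iteration, value.var = "se")
  iters <- sort(unique(tr$iteration))
  out <- rbindlist(lapply(iters[-1], function(it) {
    a <- wide[[as.character(it)]]
    b <- wide[[as.character(it - 1L)]]
    s <- wse[[as.character(it)]]
    z <- abs(a - b) / (sqrt(2) * pmax(s, 1e-12))
    data.table(iteration = it, max_abs_change = max(abs(a - b), na.rm = TRUE),
               max_change_se = max(z, na.rm = TRUE))
  }))
  setattr(out, "tol_se", tol_se)
  out[]
}

#' Mask-and-recover validation of the imputation algorithm
#'
#' Starting from a complete grid, masks a random fraction of interior cells
#' (never a patient's first or last index, so every masked cell stays inside
#' its follow-up window), runs the full multiple imputation, and reports the
#' RMSE of the pooled (mean over `m`) imputations against the hidden truth,
#' the RMSE of plain column-mean imputation on the same mask, and the
#' fraction of truths inside the 2.5--97.5% range of the `m` draws.
#'
#' @param complete_grid long table `patient_id`, `t_index`, `value`, no
#'   missing cells (e.g. a simulated `true_grid`).
#' @param covariates optional covariate table.
#' @param mask_fraction fraction of maskable cells to hide, in (0, 1).
#' @param seed integer seed (masking and imputation).
#' @param burnin,m,... passed to [run_multiple_imputation()].
#' @return list with `rmse`, `colmean_rmse`, `coverage`, `n_masked`, and the
#'   masked cell table.  With an empty mask all metrics are `NA`.
#' @export
mask_and_recover <- function(complete_grid, covariates = NULL,
                             mask_fraction = 0.1, seed = 1L,
                             burnin = 15L, m = 10L, ...) {
  stop_if(mask_fraction <= 0 || mask_fraction >= 1,
          "mask_fraction must be in (0, 1)")
  g <- as.data.table(complete_grid)
  stop_if(anyNA(g$value), "complete_grid must have no missing values")
  g <- g[order(patient_id, t_index)]
  g[, `:=`(first = t_index == min(t_index), last = t_index == max(t_index)),
    by = patient_id]
  maskable <- which(!g$first & !g$last)
  set.seed(derive_seed(seed, 31L))
  n_mask <- floor(length(maskable) * mask_fraction)
  if (n_mask == 0L)
    return(list(rmse = NA_real_, colmean_rmse = NA_real_,
                coverage = NA_real_, n_masked = 0L, masked = g[0]))
  hide <- sort(sample(maskable, n_mask))
  masked <- copy(g)[, c("first", "last") := NULL]
  truth <- masked$value[hide]
  masked$value[hide] <- NA_real_
  imp <- run_multiple_imputation(masked, covariates, burnin = burnin, m = m,
                                 seed = seed, ...)
  key_cols <- g[hide, .(patient_id, t_index)]
  draws <- sapply(imp$datasets, function(d)
    d[key_cols, on = c("patient_id", "t_index")]$value)
  draws <- matrix(draws, nrow = n_mask)
  pooled <- rowMeans(draws)
  qs <- t(apply(draws, 1L, quantile, probs = c(0.025, 0.975)))
  mu_at <- imp$mu[g$t_index[hide] + 1L]
  list(rmse = sqrt(mean((pooled - truth)^2)),
       colmean_rmse = sqrt(mean((mu_at - truth)^2)),
       coverage = mean(truth >= qs[, 1] & truth <= qs[, 2]),
       n_masked = n_mask,
       masked = cbind(key_cols, truth = truth, pooled = pooled))
}
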