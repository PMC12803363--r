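## Forecasting: feature construction, patient splits, learners ----------------

#' Build the forecasting feature table
#'
#' Emits one row per usable prediction origin `(patient, t)` under one of two
#' feature specifications:
#'
#' * **full** ("Full Information"): current and two prior values
#'   (`y_t`, `y_lag1`, `y_lag2`), adherence over the current and previous
#'   interval (`adh_t`, `adh_lag1`), `age_at_dx`, and `time_since_dx`
#'   (`grid_days * t`).
#' * **skipped** ("Skipped Last Visit"): drops `y_lag1` entirely and adds the
#'   six-month change `d6 = y_t - y_lag2`, emulating an intentionally
#'   extended monitoring interval.
#'
#' The target is the value `horizon` grid steps ahead.  Rows require
#' `t >= 2` and `t + horizon` inside the patient's grid; rows whose adherence
#' indices are unavailable are dropped (count reported via attribute
#' `n_dropped`).  `adh_t` is the adherence over `[g(t-1), gt)`, the interval
#' ending at the prediction origin.
#'
#' @param grid complete long grid (`patient_id`, `t_index`, `value`) with no
#'   missing values — run the imputation first.
#' @param adherence table `patient_id`, `t_index`, `adherence` (interval
#'   index: interval `j` covers `[g j, g (j+1))`).
#' @param covariates table with at least `patient_id`, `age_at_dx`.
#' @param spec `"full"` or `"skipped"`.
#' @param horizon 1 (one grid step, 3 months) or 2 (6 months).
#' @param grid_days grid spacing used for `time_since_dx`.
#' @return `data.table` of feature rows with attributes `spec`, `horizon`.
#' @export
build_features <- function(grid, adherence, covariates,
                           spec = c("full", "skipped"), horizon = 1L,
                           grid_days = 90L) {
  spec <- match.arg(spec)
  stop_if(!horizon %in% c(1L, 2L), "horizon must be 1 or 2")
  g <- as.data.table(grid)[, .(patient_id, t_index, value)]
  stop_if(anyNA(g$value), "grid has missing values; run imputation first")
  setorder(g, patient_id, t_index)
  g[, {
    stop_if(any(diff(t_index) != 1L), "grid indices must be contiguous per patient")
  }, by = patient_id]
  g[, `:=`(y_lag1 = shift(value, 1L), y_lag2 = shift(value, 2L),
           target = shift(value, -horizon)), by = patient_id]
  setnames(g, "value", "y_t")

  adh <- as.data.table(adherence)[, .(patient_id, t_index, adherence)]
  g[, `:=`(tm1 = t_index - 1L, tm2 = t_index - 2L)]
  a1 <- adh[, .(patient_id, tm1 = t_index, adh_t = adherence)]
  a2 <- adh[, .(patient_id, tm2 = t_index, adh_lag1 = adherence)]
  g <- a1[g, on = c("patient_id", "tm1")]
  g <- a2[g, on = c("patient_id", "tm2")]
  g[, c("tm1", "tm2") := NULL]

  cv <- as.data.table(covariates)[, .(patient_id, age_at_dx)]
  g <- cv[g, on = "patient_id"]
  g[, time_since_dx := as.numeric(grid_days) * t_index]

  eligible <- g[t_index >= 2L & !is.na(target) & !is.na(y_lag2)]
  n_eligible <- nrow(eligible)
  out <- eligible[!is.na(adh_t) & !is.na(adh_lag1) & !is.na(age_at_dx)]
  if (spec == "skipped") {
    out[, d6 := y_t - y_lag2]
    cols <- c("patient_id", "t_index", "y_t", "d6", "adh_t", "adh_lag1",
              "age_at_dx", "time_since_dx", "target")
  } else {
    cols <- c("patient_id", "t_index", "y_t", "y_lag1", "y_lag2", "adh_t",
              "adh_lag1", "age_at_dx", "time_since_dx", "target")
  }
  out <- out[, ..cols]
  setattr(out, "spec", spec)
  setattr(out, "horizon", as.integer(horizon))
  setattr(out, "n_dropped", n_eligible - nrow(out))
  out[]
}

#' Patient-level train/test split
#'
#' Deterministic under `seed`; the same assignment must be reused across all
#' imputed datasets, learners, specifications and horizons.
#'
#' @param patient_ids vector of unique patient ids (>= 5).
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return `data.table` (`patient_id`, `role` in TRAIN/TEST) of class
#'   `split_assignment`.
#' @export
split_patients <- function(patient_ids, fraction = 0.8, seed = 1L) {
  ids <- unique(patient_ids)
  stop_if(length(ids) < 5L, "need at least 5 patients to split")
  stop_if(fraction <= 0 || fraction >= 1, "fraction must be in (0, 1)")
  set.seed(derive_seed(seed, 77L))
  n_train <- round(fraction * length(ids))
  n_train <- min(max(n_train, 1L), length(ids) - 1L)
  train <- sample(ids, n_train)
  out <- data.table(patient_id = ids,
                    role = ifelse(ids %in% train, "TRAIN", "TEST"))
  setattr(out, "class", c("split_assignment", class(out)))
  setattr(out, "seed", as.integer(seed))
  out[]
}

feature_columns <- function(rows) {
  setdiff(names(rows), c("patient_id", "t_index", "target"))
}

## columns fed to the learners after z-scoring (biomarker-scale columns are
## already standardized log-ratios and are passed through untouched)
SCALED_COLS <- c("adh_t", "adh_lag1", "age_at_dx", "time_since_dx")

scale_build <- function(rows) {
  cols <- intersect(SCALED_COLS, names(rows))
  ctr <- vapply(cols, function(cn) mean(rows[[cn]]), numeric(1))
  scl <- vapply(cols, function(cn) {
    s <- sd(rows[[cn]])
    if (!is.finite(s) || s < 1e-12) 1 else s
  }, numeric(1))
  list(cols = cols, center = ctr, scale = scl)
}

scale_apply <- function(rows, sc) {
  out <- copy(as.data.table(rows))
  for (cn in sc$cols)
    out[[cn]] <- (out[[cn]] - sc$center[[cn]]) / sc$scale[[cn]]
  out
}

default_hyper <- function(learner) {
  if (learner == "xgboost")
    list(nrounds = 500L, eta = 0.05, max_depth = 4L, min_node = 10L,
         lambda = 1, subsample = 1, patience = 25L)
  else
    list(hidden = 32L, epochs = 300L, lr = 0.01, patience = 25L, l2 = 1e-5)
}

## sequence matrix consumed by the recurrent learner: the ordered lag window
rnn_sequence <- function(rows, spec) {
  if (spec == "full")
    cbind(rows$y_lag2, rows$y_lag1, rows$y_t)
  else
    cbind(rows$y_t - rows$d6, rows$y_t)    # (y_{t-2}, y_t)
}

rnn_statics <- function(rows) {
  as.matrix(rows[, intersect(SCALED_COLS, names(rows)), with = FALSE])
}

#' Train a forecasting learner
#'
#' Trains one of the two supported learners on a feature table from
#' [build_features()]:
#' `"xgboost"` — gradient-boosted regression trees (squared loss, L2 leaf
#' regularization, early stopping); `"rnn"` — a single-layer tanh recurrent
#' network consuming the ordered lag window as a length-3 (full) or length-2
#' (skipped) sequence with static covariates concatenated at the readout.
#' Early stopping for both uses a 10% validation split of the training
#' patients.  Static covariates are z-scored with training-set statistics;
#' biomarker-scale features are passed through unscaled.
#'
#' @param train_rows feature table (training rows only).
#' @param learner `"xgboost"` or `"rnn"`.
#' @param hyperparams named list overriding the defaults
#'   (xgboost: `nrounds` 500, `eta` 0.05, `max_depth` 4, `min_node` 10,
#'   `lambda` 1; rnn: `hidden` 32, `epochs` 300, `lr` 0.01).
#' @param seed integer seed (initialization, validation split).
#' @return object of class `trained_learner` supporting
#'   `predict(model, newdata)`.
#' @export
train_learner <- function(train_rows, learner = c("xgboost", "rnn"),
                          hyperparams = list(), seed = 1L) {
  learner <- match.arg(learner)
  rows <- as.data.table(train_rows)
  stop_if(nrow(rows) == 0L, "empty training data")
  spec <- attr(train_rows, "spec") %||%
    (if ("d6" %in% names(rows)) "skipped" else "full")
  hp <- utils::modifyList(default_hyper(learner), hyperparams)
  sc <- scale_build(rows)
  srows <- scale_apply(rows, sc)
  stop_if(anyNA(srows), "NaN/NA in features or target")

  set.seed(derive_seed(seed, 13L))
  ## validation split by patient for early stopping
  ids <- unique(rows$patient_id)
  val_ids <- if (length(ids) >= 10L)
    sample(ids, max(1L, floor(0.1 * length(ids)))) else character(0)
  val_idx <- which(rows$patient_id %in% val_ids)
  if (length(val_idx) == nrow(rows)) val_idx <- integer(0)

  fit <- if (learner == "xgboost") {
    X <- as.matrix(srows[, feature_columns(srows), with = FALSE])
    gbt_train(X, srows$target, nrounds = hp$nrounds, eta = hp$eta,
              max_depth = hp$max_depth, min_node = hp$min_node,
              lambda = hp$lambda, subsample = hp$subsample,
              patience = hp$patience, val_idx = val_idx)
  } else {
    rnn_train(rnn_sequence(srows, spec), rnn_statics(srows), srows$target,
              hidden = hp$hidden, epochs = hp$epochs, lr = hp$lr,
              val_idx = val_idx, patience = hp$patience, l2 = hp$l2)
  }
  structure(list(learner = learner, fit = fit, spec = spec,
                 horizon = attr(train_rows, "horizon"),
                 features = feature_columns(rows), scaling = sc,
                 hyper = hp, seed = as.integer(seed),
                 train_rows = rows),
            class = "trained_learner")
}

#' @export
predict.trained_learner <- function(object, newdata, ...) {
  rows <- scale_apply(as.data.table(newdata), object$scaling)
  missing_cols <- setdiff(object$features, names(rows))
  stop_if(length(missing_cols) > 0,
          paste("feature schema mismatch; missing:",
                paste(missing_cols, collapse = ", ")))
  if (object$learner == "xgboost")
    gbt_predict(object$fit, as.matrix(rows[, object$features, with = FALSE]))
  else
    rnn_predict(object$fit, rnn_sequence(rows, object$spec), rnn_statics(rows))
}

#' @export
print.trained_learner <- function(x, ...) {
  cat(sprintf("trained_learner: %s, spec = %s, horizon = %s, %d training rows\n",
              x$learner, x$spec, x$horizon %||% NA, nrow(x$train_rows)))
  invisible(x)
}

#' Point predictions with a within-imputation variance
#'
#' Rubin pooling needs an uncertainty for each prediction inside a single
#' imputed dataset.  The default estimator refits the learner on `B`
#' bootstrap resamples of the training *patients* and takes the variance of
#' the ensemble's predictions.  For the tree learner a cheap alternative
#' (`"tree_subsample"`) uses the spread of predictions from random
#' half-subsets of the boosted trees.
#'
#' @param model a [train_learner()] result.
#' @param rows feature rows to predict (typically the test set).
#' @param method `"bootstrap"` (default) or `"tree_subsample"`.
#' @param B ensemble size (default 20; `B < 2` yields zero variance).
#' @param seed integer seed for the ensemble.
#' @return `data.table` with `patient_id`, `t_index`, `prediction`,
#'   `within_variance`, `target`.
#' @export
predict_with_uncertainty <- function(model, rows,
                                     method = c("bootstrap", "tree_subsample"),
                                     B = 20L, seed = 1L) {
  method <- match.arg(method)
  rows <- as.data.table(rows)
  point <- predict(model, rows)
  wv <- rep(0, nrow(rows))
  if (B >= 2L && method == "bootstrap") {
    ids <- unique(model$train_rows$patient_id)
    ens <- matrix(NA_real_, nrow(rows), B)
    for (b in seq_len(B)) {
      set.seed(derive_seed(seed, 900L + b))
      boot_ids <- sample(ids, length(ids), replace = TRUE)
      boot_rows <- rbindlist(lapply(seq_along(boot_ids), function(k)
        model$train_rows[patient_id == boot_ids[k]]))
      setattr(boot_rows, "spec", model$spec)
      setattr(boot_rows, "horizon", model$horizon)
      mb <- train_learner(boot_rows, model$learner, model$hyper,
                          seed = derive_seed(seed, 950L + b))
      ens[, b] <- predict(mb, rows)
    }
    wv <- apply(ens, 1L, var)
  } else if (B >= 2L && method == "tree_subsample") {
    stop_if(model$learner != "xgboost",
            "tree_subsample variance applies to the tree learner only")
    srows <- scale_apply(rows, model$scaling)
    X <- as.matrix(srows[, model$features, with = FALSE])
    n_tree <- length(model$fit$trees)
    ens <- matrix(NA_real_, nrow(rows), B)
    for (b in seq_len(B)) {
      set.seed(derive_seed(seed, 900L + b))
      sub <- sample(n_tree, max(1L, n_tree %/% 2L))
      half <- gbt_predict(model$fit, X, trees = sub)
      ## rescale the boosted increment to full-ensemble scale
      ens[, b] <- model$fit$base + (half - model$fit$base) * n_tree / length(sub)
    }
    wv <- apply(ens, 1L, var)
  }
  data.table(patient_id = rows$patient_id, t_index = rows$t_index,
             prediction = point, within_variance = wv,
             target = rows$target)
}
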