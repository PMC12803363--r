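## Pipeline orchestration -----------------------------------------------------

#' Pipeline configuration
#'
#' Validated parameter set for [run_stage()] / [run_all()].  Defaults follow
#' the framework's stated schedule: 90-day grid, 45-day matching window,
#' 15 burn-in sweeps, 10 imputed datasets, 80/20 patient-level split.
#'
#' @param out_dir directory for all stage artifacts (created if needed).
#' @param seed master integer seed; every stage derives its own stream.
#' @param n_patients cohort size for the simulate stage.
#' @param grid_days,match_window_days alignment parameters.
#' @param log_base `"natural"` or `"base10"` standardization log.
#' @param burnin,m imputation parameters.
#' @param train_fraction patient-level training fraction.
#' @param learners,specs,horizons which forecasting cells to run.
#' @param ensemble_B bootstrap ensemble size for within-imputation
#'   prediction variance.
#' @param ensemble_method `"bootstrap"` or `"tree_subsample"`.
#' @param learner_hyperparams named list (`xgboost`, `rnn`) of hyperparameter
#'   overrides passed to [train_learner()].
#' @param sim named list of overrides for [sim_config()].
#' @param verbose print per-stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "trajmi_out", seed = 1L,
                            n_patients = 200L, grid_days = 90L,
                            match_window_days = 45L,
                            log_base = c("natural", "base10"),
                            burnin = 15L, m = 10L, train_fraction = 0.8,
                            learners = c("xgboost", "rnn"),
                            specs = c("full", "skipped"),
                            horizons = c(1L, 2L),
                            ensemble_B = 10L,
                            ensemble_method = c("bootstrap", "tree_subsample"),
                            learner_hyperparams = list(),
                            sim = list(), verbose = TRUE) {
  log_base <- match.arg(log_base)
  ensemble_method <- match.arg(ensemble_method)
  stop_if(!all(learners %in% c("xgboost", "rnn")), "unknown learner")
  stop_if(!all(specs %in% c("full", "skipped")), "unknown spec")
  stop_if(!all(horizons %in% c(1L, 2L)), "horizons must be 1 and/or 2")
  stop_if(train_fraction <= 0 || train_fraction >= 1,
          "train_fraction must be in (0, 1)")
  stop_if(burnin < 0 || m < 1 || grid_days <= 0 || match_window_days < 0,
          "invalid numeric pipeline parameter")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_patients = as.integer(n_patients),
              grid_days = as.integer(grid_days),
              match_window_days = as.integer(match_window_days),
              log_base = log_base, burnin = as.integer(burnin),
              m = as.integer(m), train_fraction = train_fraction,
              learners = learners, specs = specs,
              horizons = as.integer(horizons),
              ensemble_B = as.integer(ensemble_B),
              ensemble_method = ensemble_method,
              learner_hyperparams = learner_hyperparams,
              sim = sim, verbose = isTRUE(verbose))
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines are `key = value`; `#` starts a comment.  List-valued keys
#' (`learners`, `specs`, `horizons`) take comma-separated values; keys with a
#' `sim.` prefix override [sim_config()] fields.  Unknown keys are rejected.
#'
#' @param path configuration file.
#' @param ... overrides applied after the file is read.
#' @return a [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path, ...) {
  stop_if(!file.exists(path), paste("config file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stop_if(any(lengths(kv) != 2L), "config lines must be 'key = value'")
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  args <- list()
  sim <- list()
  numeric_keys <- c("seed", "n_patients", "grid_days", "match_window_days",
                    "burnin", "m", "train_fraction", "ensemble_B")
  list_keys <- c("learners", "specs", "horizons")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (startsWith(k, "sim.")) {
      sim[[sub("^sim\\.", "", k)]] <- as.numeric(v)
    } else if (k %in% numeric_keys) {
      args[[k]] <- as.numeric(v)
    } else if (k %in% list_keys) {
      parts <- trimws(strsplit(v, ",")[[1]])
      args[[k]] <- if (k == "horizons") as.integer(parts) else parts
    } else if (k %in% c("out_dir", "log_base", "ensemble_method")) {
      args[[k]] <- v
    } else if (k == "verbose") {
      args[[k]] <- toupper(v) %in% c("TRUE", "1", "YES")
    } else stop("unknown config key: ", k, call. = FALSE)
  }
  if (length(sim)) args$sim <- sim
  args <- utils::modifyList(args, list(...))
  do.call(pipeline_config, args)
}

pipe_path <- function(cfg, file) file.path(cfg$out_dir, file)

say <- function(cfg, fmt, ...) {
  if (cfg$verbose) message(sprintf("[trajmi] %s", sprintf(fmt, ...)))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(cfg)), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(cfg, stage, inputs, outputs, rows = list()) {
  man <- list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg),
              inputs = as.list(tools::md5sum(inputs)),
              outputs = as.list(tools::md5sum(outputs)), rows = rows)
  jsonlite::write_json(man, pipe_path(cfg, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE)
}

PIPELINE_STAGES <- c("simulate", "preprocess", "adherence", "impute",
                     "forecast", "evaluate")

#' Run one pipeline stage
#'
#' Stages read their inputs from `config$out_dir`, validate them against the
#' fixed CSV schemas, write their outputs, and record a manifest with the
#' config hash, seed and input/output checksums.  Stage order:
#' simulate, preprocess, adherence, impute, forecast, evaluate.
#'
#' @param stage stage name (see `PIPELINE_STAGES`).
#' @param config a [pipeline_config()] object.
#' @return invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, PIPELINE_STAGES)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         simulate = stage_simulate(cfg),
         preprocess = stage_preprocess(cfg),
         adherence = stage_adherence(cfg),
         impute = stage_impute(cfg),
         forecast = stage_forecast(cfg),
         evaluate = stage_evaluate(cfg))
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()] object.
#' @return invisibly, the parsed `summary.json` of the final stage.
#' @export
run_all <- function(config) {
  for (s in PIPELINE_STAGES) run_stage(s, config)
  invisible(jsonlite::read_json(pipe_path(config, "summary.json")))
}

stage_simulate <- function(cfg) {
  say(cfg, "simulate: %d patients", cfg$n_patients)
  sim_args <- utils::modifyList(
    list(n_patients = cfg$n_patients, grid_days = cfg$grid_days,
         seed = derive_seed(cfg$seed, 1L)),
    cfg$sim)
  cohort <- simulate_cohort(do.call(sim_config, sim_args))
  outs <- c(
    write_stage_csv(cohort$measurements[, .(patient_id, day, raw_value, assay_format)],
                    pipe_path(cfg, "measurements.csv")),
    write_stage_csv(cohort$treatment, pipe_path(cfg, "treatment.csv")),
    write_stage_csv(cohort$dispensations, pipe_path(cfg, "dispensations.csv")),
    write_stage_csv(cohort$covariates[, .(patient_id, age_at_dx, bmi, sex,
                                          first_line_treatment)],
                    pipe_path(cfg, "covariates.csv")),
    write_stage_csv(cohort$true_grid, pipe_path(cfg, "true_grid.csv")))
  write_manifest(cfg, "simulate", character(0), outs,
                 list(measurements = nrow(cohort$measurements)))
  invisible(outs)
}

stage_preprocess <- function(cfg) {
  ins <- pipe_path(cfg, c("measurements.csv", "treatment.csv"))
  meas <- read_validated(ins[1], "measurements")
  treat <- read_validated(ins[2], "treatment")
  medians <- format_median_table(meas, treat)
  std <- standardize(meas, medians, treat, log_base = cfg$log_base)
  aligned <- align_to_grid(std, grid_days = cfg$grid_days,
                           match_window_days = cfg$match_window_days)
  say(cfg, "preprocess: %d grid cells, %.1f%% missing", nrow(aligned),
      100 * mean(is.na(aligned$value)))
  out <- write_stage_csv(aligned[, .(patient_id, t_index, value, matched_day)],
                         pipe_path(cfg, "aligned.csv"))
  write_manifest(cfg, "preprocess", ins, out, list(aligned = nrow(aligned)))
  invisible(out)
}

stage_adherence <- function(cfg) {
  ins <- pipe_path(cfg, c("dispensations.csv", "aligned.csv"))
  disp <- read_validated(ins[1], "dispensations")
  aligned <- read_validated(ins[2], "aligned")
  ends <- aligned[, .(end = (max(t_index) + 1L) * cfg$grid_days), by = patient_id]
  ends_v <- setNames(as.list(ends$end), ends$patient_id)
  adh <- compute_adherence(disp, observation_end = ends_v,
                           grid_days = cfg$grid_days)
  ## patients with dispensation records but no aligned rows are dropped,
  ## patients with no fills get all-zero trajectories
  nofill <- setdiff(ends$patient_id, unique(adh$patient_id))
  if (length(nofill)) {
    extra <- rbindlist(lapply(nofill, function(p)
      data.table(patient_id = p,
                 t_index = 0:(ends_v[[p]] %/% cfg$grid_days - 1L),
                 adherence = 0)))
    adh <- rbind(adh, extra)
  }
  adh <- adh[patient_id %in% ends$patient_id]
  say(cfg, "adherence: mean CMA9 %.3f", mean(adh$adherence))
  out <- write_stage_csv(adh, pipe_path(cfg, "adherence.csv"))
  write_manifest(cfg, "adherence", ins, out, list(adherence = nrow(adh)))
  invisible(out)
}

stage_impute <- function(cfg) {
  ins <- pipe_path(cfg, c("aligned.csv", "covariates.csv"))
  aligned <- read_validated(ins[1], "aligned")
  covs <- read_validated(ins[2], "covariates")
  imp <- run_multiple_imputation(aligned, covs, burnin = cfg$burnin,
                                 m = cfg$m, seed = derive_seed(cfg$seed, 3L))
  long <- imputed_long(imp)
  long[, was_imputed := as.integer(was_imputed)]
  say(cfg, "impute: m = %d, %d imputed cells per dataset", cfg$m,
      sum(imp$datasets[[1]]$was_imputed))
  outs <- c(write_stage_csv(long, pipe_path(cfg, "imputed.csv")),
            write_stage_csv(imp$trace, pipe_path(cfg, "impute_trace.csv")))
  write_manifest(cfg, "impute", ins, outs, list(imputed = nrow(long)))
  invisible(outs)
}

stage_forecast <- function(cfg) {
  ins <- pipe_path(cfg, c("imputed.csv", "adherence.csv", "covariates.csv"))
  imputed <- read_validated(ins[1], "imputed")
  adh <- read_validated(ins[2], "adherence")
  covs <- read_validated(ins[3], "covariates")
  split <- split_patients(sort(unique(imputed$patient_id)),
                          fraction = cfg$train_fraction,
                          seed = derive_seed(cfg$seed, 4L))
  train_ids <- split[role == "TRAIN", patient_id]
  preds <- list()
  for (k in sort(unique(imputed$imputation_id))) {
    dk <- imputed[imputation_id == k]
    for (sp in cfg$specs) for (h in cfg$horizons) {
      feats <- build_features(dk, adh, covs, spec = sp, horizon = h,
                              grid_days = cfg$grid_days)
      tr_rows <- feats[patient_id %in% train_ids]
      te_rows <- feats[!patient_id %in% train_ids]
      if (nrow(tr_rows) == 0L || nrow(te_rows) == 0L) next
      setattr(tr_rows, "spec", sp); setattr(tr_rows, "horizon", as.integer(h))
      for (lr in cfg$learners) {
        mdl <- train_learner(tr_rows, lr,
                             hyperparams = cfg$learner_hyperparams[[lr]] %||% list(),
                             seed = derive_seed(cfg$seed, 40L + 7L * k + h))
        pu <- predict_with_uncertainty(
          mdl, te_rows, method = cfg$ensemble_method, B = cfg$ensemble_B,
          seed = derive_seed(cfg$seed, 400L + 13L * k + h))
        preds[[length(preds) + 1L]] <-
          cbind(imputation_id = k, learner = lr, spec = sp, horizon = h, pu)
      }
    }
    say(cfg, "forecast: imputation %d done", k)
  }
  out <- write_stage_csv(rbindlist(preds), pipe_path(cfg, "predictions.csv"))
  write_manifest(cfg, "forecast", ins, out,
                 list(predictions = nrow(rbindlist(preds))))
  invisible(out)
}

stage_evaluate <- function(cfg) {
  ins <- pipe_path(cfg, c("predictions.csv", "aligned.csv"))
  preds <- read_validated(ins[1], "predictions")
  aligned <- read_validated(ins[2], "aligned")
  target_sd <- sd(aligned$value, na.rm = TRUE)
  pooled <- pool_predictions(preds)
  report <- compute_rmse(preds)
  summ <- evaluation_summary(report, target_sd)
  outs <- c(
    write_stage_csv(pooled, pipe_path(cfg, "pooled_predictions.csv")),
    write_stage_csv(summ$table, pipe_path(cfg, "rmse_report.csv")),
    write_stage_csv(report$per_t, pipe_path(cfg, "rmse_by_time.csv")))
  js <- list(
    target_sd = target_sd,
    m = report$overall$m[1],
    overall = lapply(seq_len(nrow(summ$table)), function(i) as.list(summ$table[i])),
    orderings = lapply(seq_len(nrow(summ$orderings)), function(i)
      as.list(summ$orderings[i])))
  jsonlite::write_json(js, pipe_path(cfg, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outs <- c(outs, pipe_path(cfg, "summary.json"))
  say(cfg, "evaluate: %d configurations pooled", nrow(summ$table))
  write_manifest(cfg, "evaluate", ins, outs)
  invisible(outs)
}

#' Command-line entry point
#'
#' Dispatches `simulate | preprocess | adherence | impute | forecast |
#' evaluate | run-all` with flags `--config FILE`, `--seed N`,
#' `--out-dir DIR`, `--verbose/--quiet`.  Used by the
#' `inst/cli/trajmi.R` script:
#' `Rscript -e 'trajmi::trajmi_cli()' run-all --seed 1 --out-dir out`.
#'
#' @param args character vector of CLI arguments.
#' @return exit status (0 on success), invisibly.
#' @export
trajmi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: trajmi <simulate|preprocess|adherence|impute|forecast|evaluate|run-all>",
        "[--config FILE] [--seed N] [--out-dir DIR] [--quiet]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    adv <- function() { i <<- i + 1L; args[i] }
    switch(a,
           "--config" = { opts$config <- adv() },
           "--seed" = { opts$seed <- as.integer(adv()) },
           "--out-dir" = { opts$out_dir <- adv() },
           "--quiet" = { opts$verbose <- FALSE },
           "--verbose" = { opts$verbose <- TRUE },
           stop("unknown flag: ", a, call. = FALSE))
    i <- i + 1L
  }
  cfg <- if (!is.null(opts$config)) {
    ov <- opts[setdiff(names(opts), "config")]
    do.call(read_pipeline_config, c(list(opts$config), ov))
  } else do.call(pipeline_config, opts[setdiff(names(opts), "config")])
  if (cmd == "run-all") run_all(cfg)
  else run_stage(cmd, cfg)
  invisible(0L)
}
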