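## CSV interchange schemas and validation -------------------------------------
##
## Plain UTF-8 CSV with header is the interchange format; missing values are
## empty fields; all day quantities are integer days since diagnosis (day 0)
## and t_index is 0-based.

schema_registry <- function() {
  list(
    measurements = list(
      cols = list(
        patient_id = list(type = "character"),
        day = list(type = "integer", min = 0),
        raw_value = list(type = "numeric", min = 1e-12),
        assay_format = list(type = "character")),
      unique_by = c("patient_id", "day")),
    treatment = list(
      cols = list(
        patient_id = list(type = "character"),
        treatment_start_day = list(type = "integer")),
      unique_by = "patient_id"),
    dispensations = list(
      cols = list(
        patient_id = list(type = "character"),
        fill_day = list(type = "integer", min = 0),
        days_supplied = list(type = "integer", min = 1))),
    covariates = list(
      cols = list(
        patient_id = list(type = "character"),
        age_at_dx = list(type = "numeric", min = 18),
        bmi = list(type = "numeric", min = 5, max = 100, allow_na = TRUE),
        sex = list(type = "character", levels = c("F", "M")),
        first_line_treatment = list(type = "character",
                                    levels = c("imatinib", "dasatinib", "nilotinib"))),
      unique_by = "patient_id"),
    true_grid = list(
      cols = list(
        patient_id = list(type = "character"),
        t_index = list(type = "integer", min = 0),
        value = list(type = "numeric")),
      unique_by = c("patient_id", "t_index")),
    aligned = list(
      cols = list(
        patient_id = list(type = "character"),
        t_index = list(type = "integer", min = 0),
        value = list(type = "numeric", allow_na = TRUE),
        matched_day = list(type = "integer", allow_na = TRUE)),
      unique_by = c("patient_id", "t_index")),
    adherence = list(
      cols = list(
        patient_id = list(type = "character"),
        t_index = list(type = "integer", min = 0),
        adherence = list(type = "numeric", min = 0, max = 1)),
      unique_by = c("patient_id", "t_index")),
    imputed = list(
      cols = list(
        imputation_id = list(type = "integer", min = 1),
        patient_id = list(type = "character"),
        t_index = list(type = "integer", min = 0),
        value = list(type = "numeric"),
        was_imputed = list(type = "integer", min = 0, max = 1)),
      unique_by = c("imputation_id", "patient_id", "t_index")),
    predictions = list(
      cols = list(
        imputation_id = list(type = "integer", min = 1),
        learner = list(type = "character", levels = c("xgboost", "rnn")),
        spec = list(type = "character", levels = c("full", "skipped")),
        horizon = list(type = "integer", min = 1, max = 2),
        patient_id = list(type = "character"),
        t_index = list(type = "integer", min = 0),
        prediction = list(type = "numeric"),
        within_variance = list(type = "numeric", min = 0),
        target = list(type = "numeric")))
  )
}

#' Validate a CSV file against a named pipeline schema
#'
#' Checks column presence, type, range, factor levels, missingness and
#' uniqueness constraints.
#'
#' @param path CSV file path.
#' @param schema one of `"measurements"`, `"treatment"`, `"dispensations"`,
#'   `"covariates"`, `"true_grid"`, `"aligned"`, `"adherence"`, `"imputed"`,
#'   `"predictions"`.
#' @return `data.table` of violations (`column`, `problem`, `n_rows`);
#'   zero rows means the file is valid.
#' @export
validate_schemas <- function(path, schema) {
  reg <- schema_registry()
  stop_if(!schema %in% names(reg), paste("unknown schema:", schema))
  stop_if(!file.exists(path), paste("file not found:", path))
  sc <- reg[[schema]]
  dt <- fread(path, na.strings = "", colClasses = list(character = "patient_id"))
  bad <- list()
  note <- function(column, problem, n)
    bad[[length(bad) + 1L]] <<- data.table(column = column, problem = problem,
                                           n_rows = as.integer(n))
  miss <- setdiff(names(sc$cols), names(dt))
  for (cn in miss) note(cn, "missing column", nrow(dt))
  for (cn in setdiff(names(sc$cols), miss)) {
    rule <- sc$cols[[cn]]
    v <- dt[[cn]]
    if (rule$type %in% c("integer", "numeric") && !is.numeric(v)) {
      suppressWarnings(v2 <- as.numeric(v))
      if (any(is.na(v2) & !is.na(v))) {
        note(cn, "non-numeric values", sum(is.na(v2) & !is.na(v)))
        next
      }
      v <- v2
    }
    if (rule$type == "integer" && is.numeric(v) &&
        any(v[!is.na(v)] != round(v[!is.na(v)])))
      note(cn, "non-integer values", sum(v[!is.na(v)] != round(v[!is.na(v)])))
    if (!isTRUE(rule$allow_na) && anyNA(v))
      note(cn, "missing values not allowed", sum(is.na(v)))
    ok <- !is.na(v)
    if (!is.null(rule$min) && any(v[ok] < rule$min))
      note(cn, sprintf("values below %s", rule$min), sum(v[ok] < rule$min))
    if (!is.null(rule$max) && any(v[ok] > rule$max))
      note(cn, sprintf("values above %s", rule$max), sum(v[ok] > rule$max))
    if (!is.null(rule$levels) && any(!v[ok] %in% rule$levels))
      note(cn, "value outside allowed levels", sum(!v[ok] %in% rule$levels))
  }
  if (!is.null(sc$unique_by) && all(sc$unique_by %in% names(dt))) {
    ndup <- anyDuplicated(dt[, sc$unique_by, with = FALSE])
    if (ndup > 0)
      note(paste(sc$unique_by, collapse = "+"), "duplicate keys",
           sum(duplicated(dt[, sc$unique_by, with = FALSE])))
  }
  if (length(bad)) rbindlist(bad) else
    data.table(column = character(0), problem = character(0),
               n_rows = integer(0))
}

read_validated <- function(path, schema) {
  v <- validate_schemas(path, schema)
  if (nrow(v) > 0) {
    stop(sprintf("schema violations in %s (%s):\n%s", path, schema,
                 paste(sprintf("  - column %s: %s (%d rows)", v$column,
                               v$problem, v$n_rows), collapse = "\n")),
         call. = FALSE)
  }
  fread(path, na.strings = "", colClasses = list(character = "patient_id"))
}

write_stage_csv <- function(dt, path) {
  fwrite(dt, path, na = "")
  path
}
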