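#' Build a cohort object from a patients-by-variables data frame
#'
#' A cohort is the single input object of the triad-screening pipeline: a
#' tibble with one row per patient, a `patient_id` column, a set of
#' non-negative numeric variable columns, and (optionally) survival columns
#' `time` (follow-up days) and `event` (0/1, 1 = death). Variable roles and
#' the missing/negative-value policies are carried as attributes so every
#' downstream stage sees the same contract.
#'
#' @param data A data frame; one row per patient.
#' @param variables Character vector of variable column names. Default: all
#'   numeric columns not claimed by `patient_id`, `time` or `event`.
#' @param patient_id Name of an identifier column, or `NULL` to generate
#'   `P1..Pn`.
#' @param time,event Names of the follow-up-time and event-indicator
#'   columns; both or neither must be given.
#' @param missing Missing-value policy: `"error"` rejects any `NA` in a
#'   variable column (the default; explicit failure beats silent
#'   imputation), `"pairwise"` drops the variable within an affected
#'   patient-pair comparison and renormalises the distance over the
#'   observed variables.
#' @param negatives Negative-value policy: `"error"` (default; the
#'   Marczewski-Steinhaus ratio is undefined in sign-mixed data) or
#'   `"shift"`, which subtracts each offending column's minimum.
#'
#' @return A tibble of class `ms_cohort`.
#' @export
#' @examples
#' df <- data.frame(a = c(1, 2, 3, 4), b = c(2, 2, 1, 5), c = c(0, 1, 1, 2))
#' as_cohort(df)
as_cohort <- function(data, variables = NULL, patient_id = NULL,
                      time = NULL, event = NULL,
                      missing = c("error", "pairwise"),
                      negatives = c("error", "shift")) {
  missing <- match.arg(missing)
  negatives <- match.arg(negatives)
  data <- as_tibble(data)

  if (xor(is.null(time), is.null(event))) {
    abort("`time` and `event` must be supplied together or not at all.")
  }
  for (col in c(patient_id, time, event)) {
    if (!col %in% names(data)) abort(paste0("Column '", col, "' not found."))
  }
  if (is.null(variables)) {
    claimed <- c(patient_id, time, event)
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
    variables <- setdiff(variables, claimed)
  } else if (!all(variables %in% names(data))) {
    abort(paste0("Unknown variable column(s): ",
                 paste(setdiff(variables, names(data)), collapse = ", ")))
  }
  if (anyDuplicated(variables)) {
    abort("Duplicated variable names are not allowed.")
  }
  if (length(variables) < 3) {
    abort("A cohort needs at least 3 variables (one triad).")
  }
  if (nrow(data) < 4) {
    abort("A cohort needs at least 4 patients.")
  }

  ids <- if (is.null(patient_id)) paste0("P", seq_len(nrow(data)))
         else as.character(data[[patient_id]])
  if (anyDuplicated(ids)) abort("Patient identifiers must be unique.")

  for (v in variables) {
    col <- data[[v]]
    if (!is.numeric(col)) {
      bad <- which(!vapply(col, function(x) {
        is.na(x) || !is.na(suppressWarnings(as.numeric(x)))
      }, logical(1)))[1]
      abort(paste0("Non-numeric value in column '", v, "', row ",
                   if (is.na(bad)) "?" else bad, "."))
    }
    if (missing == "error" && anyNA(col)) {
      abort(paste0("Missing value in column '", v, "', row ",
                   which(is.na(col))[1],
                   "' (missing policy is 'error')."))
    }
    if (any(col < 0, na.rm = TRUE)) {
      if (negatives == "error") {
        abort(paste0("Negative value in column '", v, "', row ",
                     which(col < 0)[1],
                     " (negative policy is 'error')."))
      }
      data[[v]] <- col - min(col, na.rm = TRUE)
    }
  }

  if (!is.null(time)) {
    tv <- data[[time]]; ev <- data[[event]]
    if (!is.numeric(tv) || any(tv < 0, na.rm = TRUE)) {
      abort("`time` must be a non-negative numeric column.")
    }
    if (!all(ev %in% c(0, 1, NA))) abort("`event` must contain only 0/1.")
  }

  out <- data
  out$patient_id <- ids
  out <- dplyr::relocate(out, "patient_id")
  structure(out,
            class = c("ms_cohort", class(as_tibble(out))),
            ms_variables = variables,
            ms_time = time, ms_event = event,
            ms_missing = missing, ms_negatives = negatives)
}

#' @export
print.ms_cohort <- function(x, ...) {
  vars <- attr(x, "ms_variables")
  cat("<ms_cohort> ", nrow(x), " patients x ", length(vars), " variables",
      if (!is.null(attr(x, "ms_time"))) "  (+ survival columns)", "\n",
      sep = "")
  NextMethod()
}

cohort_variables <- function(cohort) attr(cohort, "ms_variables")

cohort_values <- function(cohort) {
  vars <- cohort_variables(cohort)
  m <- as.matrix(as.data.frame(cohort)[vars])
  rownames(m) <- cohort$patient_id
  m
}

cohort_missing_policy <- function(cohort) attr(cohort, "ms_missing") %||% "error"

has_survival <- function(cohort) !is.null(attr(cohort, "ms_time"))

cohort_survival <- function(cohort) {
  if (!has_survival(cohort)) abort("Cohort has no survival columns.")
  list(time = cohort[[attr(cohort, "ms_time")]],
       event = cohort[[attr(cohort, "ms_event")]])
}

#' Read a cohort from a CSV file
#'
#' Expects an RFC-4180 CSV with a header row, `.` decimal separator, and
#' numeric variable columns. The schema names the column roles and
#' policies; it may be a list or a path to a YAML file with the same
#' fields (`variables`, `patient_id`, `time`, `event`, `missing`,
#' `negatives`).
#'
#' @param path CSV file path.
#' @param schema Optional list or YAML file path of column roles.
#' @return An [as_cohort()] tibble.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (is.character(schema) && length(schema) == 1) {
    schema <- yaml::read_yaml(schema)
  }
  schema <- schema %||% list()
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  vars <- schema$variables
  if (!is.null(vars)) {
    for (v in vars) {
      if (!v %in% names(raw)) abort(paste0("Schema variable '", v, "' not in file."))
      if (!is.numeric(raw[[v]])) {
        chr <- as.character(raw[[v]])
        num <- suppressWarnings(as.numeric(chr))
        bad <- which(is.na(num) & !is.na(chr))[1]
        if (!is.na(bad)) {
          abort(paste0("Cannot parse '", chr[bad], "' as numeric in column '",
                       v, "', row ", bad, "."))
        }
        raw[[v]] <- num
      }
    }
  }
  as_cohort(raw, variables = vars,
            patient_id = schema$patient_id,
            time = schema$time, event = schema$event,
            missing = schema$missing %||% "error",
            negatives = schema$negatives %||% "error")
}

#' Write a cohort to CSV
#'
#' Numeric variable columns are rounded to `digits` significant digits
#' before writing, giving byte-stable output at a declared precision;
#' with the default 15 digits the numeric matrix round-trips exactly
#' through [read_cohort()].
#'
#' @param cohort An `ms_cohort`.
#' @param path Output file path.
#' @param digits Significant digits retained (default 15).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, digits = 15) {
  out <- as_tibble(cohort)
  for (v in cohort_variables(cohort)) out[[v]] <- signif(out[[v]], digits)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-variable descriptive statistics
#'
#' One row per variable: mean, median, sample SD (n-1 denominator), IQR,
#' range, coefficient of variation (sd/mean, reported when the mean is
#' positive), and the p-value of a Kolmogorov-Smirnov test against a
#' normal distribution with the sample's own mean and SD. A zero-variance
#' variable gets `cv` computed and `ks_p = NA` (the test is undefined).
#'
#' @param cohort An `ms_cohort`.
#' @return A tibble with columns `name`, `mean`, `median`, `sd`, `iqr`,
#'   `min`, `max`, `cv`, `ks_p`.
#' @export
describe_cohort <- function(cohort) {
  vars <- cohort_variables(cohort)
  purrr::map_dfr(vars, function(v) {
    x <- cohort[[v]]
    x <- x[!is.na(x)]
    m <- mean(x); s <- sd(x)
    ks <- if (s > 0) {
      suppressWarnings(ks.test(x, "pnorm", mean = m, sd = s)$p.value)
    } else NA_real_
    tibble(name = v, mean = m, median = median(x), sd = s,
           iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
           min = min(x), max = max(x),
           cv = if (m > 0) s / m else NA_real_,
           ks_p = ks)
  })
}
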