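#' Moment-match a sampling family to a target mean and SD
#'
#' Returns parameters such that the *untruncated* distribution has exactly
#' the requested mean and standard deviation. For the lognormal family,
#' `mu = log(m^2 / sqrt(m^2 + s^2))` and `sigma^2 = log(1 + s^2/m^2)`;
#' for the (to-be-truncated) normal family the parameters are the targets
#' themselves. Truncation to a variable's observed range introduces a
#' small moment bias that the generator tolerates by design.
#'
#' @param family `"lognormal"` or `"normal-truncated"`.
#' @param target_mean,target_sd Positive targets.
#' @return A named list of distribution parameters.
#' @export
#' @examples
#' moment_match("lognormal", 40.7, 50.0)
moment_match <- function(family = c("lognormal", "normal-truncated"),
                         target_mean, target_sd) {
  family <- match.arg(family)
  if (target_mean <= 0) abort("`target_mean` must be positive.")
  if (target_sd < 0) abort("`target_sd` must be non-negative.")
  if (family == "lognormal") {
    s2 <- log(1 + target_sd^2 / target_mean^2)
    list(meanlog = log(target_mean) - s2 / 2, sdlog = sqrt(s2))
  } else {
    list(mean = target_mean, sd = target_sd)
  }
}

#' Specify a synthetic cohort
#'
#' `variables` is a tibble with one row per variable: `name`, `family`
#' (`"lognormal"` or `"normal-truncated"`), `target_mean`, `target_sd`,
#' `lower`, `upper` and `disease_coupling` (>= 0; a multiplicative SD
#' inflation factor `1 + disease_coupling` applied within the event
#' subgroup, emulating disease-driven dispersion of active markers).
#' Right-skewed variables (`target_sd/target_mean` above `skew_threshold`)
#' must use the lognormal family.
#'
#' @param variables Tibble of per-variable specifications (see Details).
#' @param n_patients Cohort size (default 366).
#' @param event_fraction Fraction of patients dying within follow-up
#'   (default 76/366).
#' @param follow_up_days Administrative censoring time (default 365).
#' @param correlation Optional positive-definite correlation matrix
#'   (unit diagonal) inducing inter-variable dependence through a Gaussian
#'   copula on the uniform ranks; default identity (independent margins).
#' @param skew_threshold Coefficient-of-variation threshold above which
#'   the lognormal family is required (default 0.6).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(variables, n_patients = 366,
                        event_fraction = 76 / 366, follow_up_days = 365,
                        correlation = NULL, skew_threshold = 0.6) {
  variables <- as_tibble(variables)
  needed <- c("name", "family", "target_mean", "target_sd", "lower", "upper")
  if (!all(needed %in% names(variables))) {
    abort(paste0("`variables` must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (!"disease_coupling" %in% names(variables)) {
    variables$disease_coupling <- 0
  }
  if (anyDuplicated(variables$name)) abort("Variable names must be unique.")
  with(variables, {
    if (any(target_sd <= 0)) abort("All `target_sd` must be positive.")
    if (any(lower < 0)) abort("All `lower` bounds must be non-negative.")
    if (any(lower >= upper)) abort("Each `lower` must be below `upper`.")
    if (any(disease_coupling < 0)) abort("`disease_coupling` must be >= 0.")
    skewed <- target_sd / target_mean > skew_threshold
    if (any(skewed & family != "lognormal")) {
      abort(paste0("Right-skewed variables require family 'lognormal': ",
                   paste(name[skewed & family != "lognormal"], collapse = ", ")))
    }
  })
  if (!all(variables$family %in% c("lognormal", "normal-truncated"))) {
    abort("`family` must be 'lognormal' or 'normal-truncated'.")
  }
  if (event_fraction <= 0 || event_fraction >= 1) {
    abort("`event_fraction` must lie strictly between 0 and 1.")
  }
  if (!is.null(correlation)) {
    p <- nrow(variables)
    if (!is.matrix(correlation) || any(dim(correlation) != p) ||
        !isTRUE(all.equal(correlation, t(correlation))) ||
        !isTRUE(all.equal(diag(correlation), rep(1, p)))) {
      abort("`correlation` must be a symmetric matrix with unit diagonal.")
    }
  }
  structure(list(variables = variables, n_patients = n_patients,
                 event_fraction = event_fraction,
                 follow_up_days = follow_up_days,
                 correlation = correlation),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_patients, " patients x ",
      nrow(x$variables), " variables; event fraction ",
      signif(x$event_fraction, 4), "\n", sep = "")
  print(x$variables, ...)
  invisible(x)
}

#' The packaged APE-panel cohort specification
#'
#' Transcribes the reference panel ([ape_panel_reference()]) into a
#' [cohort_spec()]: each variable keeps its published mean, SD and
#' observed range; variables with coefficient of variation above 0.6 use
#' the lognormal family, the rest a range-truncated normal. Defaults to
#' 366 patients with 76 events within 365 days and independent margins.
#'
#' @param planted Character vector of variable names given a positive
#'   `disease_coupling` (default none).
#' @param coupling Coupling value applied to `planted` (default 2).
#' @param n_patients,event_fraction Passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(planted = character(), coupling = 2,
                                n_patients = 366,
                                event_fraction = 76 / 366) {
  ref <- ape_panel_reference()
  if (!all(planted %in% ref$name)) {
    abort(paste0("Unknown planted variable(s): ",
                 paste(setdiff(planted, ref$name), collapse = ", ")))
  }
  vars <- tibble(
    name = ref$name,
    family = ifelse(ref$sd / ref$mean > 0.6, "lognormal", "normal-truncated"),
    target_mean = ref$mean, target_sd = ref$sd,
    lower = ref$min, upper = ref$max,
    disease_coupling = ifelse(ref$name %in% planted, coupling, 0))
  cohort_spec(vars, n_patients = n_patients, event_fraction = event_fraction)
}

# Inverse-CDF sample within [lower, upper]: exact truncation that maps the
# copula's uniform ranks monotonically onto the bounded support.
truncated_quantile <- function(u, family, params, lower, upper) {
  if (family == "lognormal") {
    flo <- plnorm(lower, params$meanlog, params$sdlog)
    fhi <- plnorm(upper, params$meanlog, params$sdlog)
    qlnorm(flo + u * (fhi - flo), params$meanlog, params$sdlog)
  } else {
    flo <- pnorm(lower, params$mean, params$sd)
    fhi <- pnorm(upper, params$mean, params$sd)
    qnorm(flo + u * (fhi - flo), params$mean, params$sd)
  }
}

# Exponential truncated to [0, span], by inverse CDF.
rtrunc_exp <- function(u, rate, span) {
  -log(1 - u * (1 - exp(-rate * span))) / rate
}

#' Generate a synthetic cohort
#'
#' Draws a patients-by-variables table from a [cohort_spec()]. Uniform
#' ranks come from a Gaussian copula (identity correlation by default),
#' then each margin is inverted through its moment-matched, range-
#' truncated family. Exactly `round(n_patients * event_fraction)` patients
#' are marked as events; variables with `disease_coupling > 0` are drawn
#' with SD inflated by `(1 + disease_coupling)` inside the event subgroup.
#' Event times follow an early-excess mixture — half the events fall in an
#' exponential window over days 0-14 (mean 5 days), the rest decay slowly
#' (mean 120 days) across the remaining follow-up — and censored patients
#' exit at `follow_up_days`. Output is bit-identical for a fixed seed.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @return An [as_cohort()] tibble with `time`/`event` columns and the
#'   seed recorded in attribute `ms_seed`.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_patients
  vars <- spec$variables
  p <- nrow(vars)

  z <- matrix(rnorm(n * p), n, p)
  if (!is.null(spec$correlation)) {
    ch <- tryCatch(chol(spec$correlation), error = function(e) {
      abort("`correlation` is not positive definite.")
    })
    z <- z %*% ch
  }
  u <- pnorm(z)

  n_events <- round(n * spec$event_fraction)
  event <- integer(n)
  event[sample.int(n, n_events)] <- 1L

  values <- matrix(0, n, p, dimnames = list(NULL, vars$name))
  for (j in seq_len(p)) {
    row <- vars[j, ]
    base <- moment_match(row$family, row$target_mean, row$target_sd)
    x <- truncated_quantile(u[, j], row$family, base, row$lower, row$upper)
    if (row$disease_coupling > 0 && n_events > 0) {
      infl <- moment_match(row$family, row$target_mean,
                           row$target_sd * (1 + row$disease_coupling))
      x[event == 1] <- truncated_quantile(u[event == 1, j], row$family,
                                          infl, row$lower, row$upper)
    }
    values[, j] <- x
  }

  fu <- spec$follow_up_days
  time <- rep(fu, n)
  if (n_events > 0) {
    idx <- which(event == 1)
    early <- runif(n_events) < 0.5
    tu <- runif(n_events)
    t_ev <- ifelse(early,
                   rtrunc_exp(tu, rate = 1 / 5, span = 14),
                   14 + rtrunc_exp(tu, rate = 1 / 120, span = fu - 14))
    time[idx] <- t_ev
  }

  out <- as_tibble(as.data.frame(values, check.names = FALSE))
  out$time <- time
  out$event <- event
  cohort <- as_cohort(out, variables = vars$name,
                      time = "time", event = "event")
  attr(cohort, "ms_seed") <- seed
  cohort
}
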