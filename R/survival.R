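#' Kaplan-Meier product-limit estimate
#'
#' Native product-limit estimator with Greenwood-based complementary
#' log-log 95% confidence bands (the transformation keeps the bands
#' inside (0, 1)). With no censoring the estimate equals the empirical
#' survivor function; with no events the curve is flat at 1 and the
#' bands are undefined (`NA`, and the result carries attribute
#' `no_events = TRUE`).
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators (1 = death).
#' @param conf_level Confidence level for the pointwise bands.
#' @return A `km_estimate` tibble: `time` (distinct event times),
#'   `at_risk`, `n_events`, `survival`, `ci_lower`, `ci_upper`.
#' @export
kaplan_meier <- function(time, event, conf_level = 0.95) {
  if (length(time) != length(event)) {
    abort("`time` and `event` must have equal length.")
  }
  if (any(time < 0)) abort("`time` must be non-negative.")
  if (!all(event %in% c(0, 1))) abort("`event` must contain only 0/1.")

  tt <- sort(unique(time[event == 1]))
  no_events <- length(tt) == 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  surv <- 1; gw <- 0
  rows <- purrr::map_dfr(tt, function(t0) {
    n_at <- sum(time >= t0)
    d <- sum(time == t0 & event == 1)
    surv <<- surv * (1 - d / n_at)
    gw <<- gw + d / (n_at * (n_at - d))
    if (surv > 0 && surv < 1 && is.finite(gw)) {
      se_cll <- sqrt(gw) / abs(log(surv))
      lo <- surv^exp(z * se_cll)
      hi <- surv^exp(-z * se_cll)
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
    tibble(time = t0, at_risk = n_at, n_events = d,
           survival = surv, ci_lower = lo, ci_upper = hi)
  })
  if (no_events) {
    rows <- tibble(time = max(time), at_risk = length(time), n_events = 0L,
                   survival = 1, ci_lower = NA_real_, ci_upper = NA_real_)
  }
  structure(rows, class = c("km_estimate", class(as_tibble(rows))),
            n = length(time), no_events = no_events,
            conf_level = conf_level)
}

#' Harrell's concordance index
#'
#' Probability that, among comparable patient pairs, the patient with the
#' higher risk score dies earlier. A pair is usable when the shorter
#' observed time is an event (standard Harrell convention for censored
#' data); tied risk scores count 0.5. Higher `score` must mean higher
#' risk.
#'
#' @param time,event As in [kaplan_meier()].
#' @param score Numeric risk scores.
#' @return Concordance in \[0, 1\].
#' @export
harrell_c <- function(time, event, score) {
  n <- length(time)
  if (length(event) != n || length(score) != n) {
    abort("`time`, `event`, `score` must have equal length.")
  }
  lt <- outer(time, time, "<")
  usable <- lt & (event == 1)          # row i dies first, observed
  if (!any(usable)) abort("No comparable pairs: concordance undefined.")
  sgt <- outer(score, score, ">")
  seq_ <- outer(score, score, "==")
  (sum(sgt & usable) + 0.5 * sum(seq_ & usable)) / sum(usable)
}

#' Akaike's information criterion from a log-likelihood
#'
#' `AIC = 2k - 2 ln(L)` with `k` the number of model parameters.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of parameters (>= 0).
#' @return The criterion value.
#' @export
#' @examples
#' aic(-174.355, 1)  # 350.71
aic <- function(loglik, k) {
  if (k < 0) abort("`k` must be non-negative.")
  2 * k - 2 * loglik
}

#' Univariate outcome-dependent screen of all cohort variables
#'
#' The classical comparison stage: for each variable a univariate Cox
#' proportional-hazards fit (via [survival::coxph()]) and a univariate
#' logistic fit for death within follow-up (via [stats::glm()]).
#' Coefficient estimation is deliberately delegated to those established
#' implementations; the concordance index is computed natively by
#' [harrell_c()] on the Cox linear predictor and the information
#' criterion natively by [aic()] on the logistic log-likelihood.
#' Non-estimable fits (e.g. an all-censored cohort) are flagged per
#' variable, not fatal.
#'
#' @param cohort An `ms_cohort` with survival columns.
#' @return A tibble with one row per variable: `variable`, `c_index`,
#'   `p_cox`, `aic`, `p_logistic`, `estimable`.
#' @export
univariate_screen <- function(cohort) {
  if (!has_survival(cohort)) abort("Cohort has no survival columns.")
  sv <- cohort_survival(cohort)
  purrr::map_dfr(cohort_variables(cohort), function(v) {
    x <- cohort[[v]]
    res <- tryCatch(suppressWarnings({
      cx <- survival::coxph(survival::Surv(sv$time, sv$event) ~ x)
      sm <- summary(cx)
      lp <- unname(cx$linear.predictors)
      ci <- harrell_c(sv$time, sv$event, lp)
      lg <- glm(sv$event ~ x, family = binomial())
      ll <- logLik(lg)
      tibble(variable = v,
             c_index = ci,
             p_cox = unname(sm$coefficients[1, "Pr(>|z|)"]),
             aic = aic(as.numeric(ll), attr(ll, "df")),
             p_logistic = summary(lg)$coefficients["x", "Pr(>|z|)"],
             estimable = is.finite(ci) && is.finite(sm$coefficients[1, "coef"]))
    }), error = function(e) {
      tibble(variable = v, c_index = NA_real_, p_cox = NA_real_,
             aic = NA_real_, p_logistic = NA_real_, estimable = FALSE)
    })
    res
  })
}
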