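# Profiled residual sum of squares for the continuous broken-stick model
#   y = a + b1*x + (b2 - b1)*(x - psi)_+
# All normal-equation entries for a given psi are linear combinations of
# suffix sums over {x > psi}, so the whole grid profile costs O(n + g).
profile_engine <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  # suffix cumulative sums: entry k = sum over observations k..n
  rc <- function(v) rev(cumsum(rev(v)))
  sx_s <- c(rc(xs), 0); sxx_s <- c(rc(xs^2), 0)
  sy_s <- c(rc(ys), 0); sxy_s <- c(rc(xs * ys), 0)
  cnt_s <- c(n:1, 0)
  n_tot <- n
  Sx <- sx_s[1]; Sxx <- sxx_s[1]; Sy <- sy_s[1]
  Sxy <- sxy_s[1]; Syy <- sum(ys^2)

  list(
    xs = xs, n = n,
    rss = function(psi) {
      # first index with xs > psi
      k <- findInterval(psi, xs, left.open = FALSE) + 1L
      cnt <- cnt_s[k]
      Sxs <- sx_s[k]; Sxxs <- sxx_s[k]
      Sys <- sy_s[k]; Sxys <- sxy_s[k]
      Sh <- Sxs - psi * cnt
      Shh <- Sxxs - 2 * psi * Sxs + psi^2 * cnt
      Sxh <- Sxxs - psi * Sxs
      Syh <- Sxys - psi * Sys
      # Cramer's rule on the 3x3 normal equations (vectorised over psi)
      m11 <- n_tot; m12 <- Sx;  m13 <- Sh
      m22 <- Sxx;  m23 <- Sxh; m33 <- Shh
      det3 <- m11 * (m22 * m33 - m23^2) -
        m12 * (m12 * m33 - m23 * m13) +
        m13 * (m12 * m23 - m22 * m13)
      a <- (Sy * (m22 * m33 - m23^2) -
              m12 * (Sxy * m33 - m23 * Syh) +
              m13 * (Sxy * m23 - m22 * Syh)) / det3
      b <- (m11 * (Sxy * m33 - Syh * m23) -
              Sy * (m12 * m33 - m23 * m13) +
              m13 * (m12 * Syh - Sxy * m13)) / det3
      d <- (m11 * (m22 * Syh - Sxy * m23) -
              m12 * (m12 * Syh - Sxy * m13) +
              Sy * (m12 * m23 - m22 * m13)) / det3
      rss <- Syy - (a * Sy + b * Sxy + d * Syh)
      rss[!is.finite(rss) | det3 == 0] <- Inf
      pmax(rss, 0)
    })
}

# Integer candidate change-points leaving at least 5 observations on
# each side of the break.
psi_grid_for <- function(xs) {
  n <- length(xs)
  lo <- ceiling(xs[5])
  hi <- ceiling(xs[n - 4]) - 1
  if (hi < lo) return(numeric(0))
  seq(lo, hi)
}

fit_segmented_xy <- function(x, y, refine = TRUE) {
  n <- length(x)
  eng <- profile_engine(x, y)
  grid <- psi_grid_for(eng$xs)
  if (!length(grid)) abort("Series too short to place a change-point.")
  rss_grid <- eng$rss(grid)
  best <- which.min(rss_grid)
  psi <- grid[best]
  rss <- rss_grid[best]
  if (refine) {
    lo <- if (best > 1) grid[best - 1] else psi - 1
    hi <- if (best < length(grid)) grid[best + 1] else psi + 1
    opt <- optimize(eng$rss, interval = c(lo, hi), tol = 1e-8)
    if (opt$objective < rss) {
      psi <- opt$minimum
      rss <- opt$objective
    }
  }
  list(psi = psi, rss = rss)
}

#' Fit a two-segment broken-stick regression to a scree series
#'
#' Estimates the continuous piecewise-linear model
#' `y = a + b1*x + (b2 - b1) * max(0, x - psi)` on the ranked triad
#' scree, locating the change-point `psi` that separates the homogeneous
#' (low-slope) from the heterogeneous (steep) triad regime. `psi` is
#' profiled exhaustively over every admissible integer rank — at each
#' candidate the remaining parameters are the least-squares solution —
#' followed by golden-section refinement between the best grid point's
#' neighbours. Slope standard errors, t-based 95% intervals and p-values
#' come from the linear model conditional on the estimated `psi`, the
#' standard segmented-regression convention.
#'
#' A zero-variance series is degenerate: the returned fit is flagged
#' (`degenerate = TRUE`) with `change_point = NA`.
#'
#' @param series An `ms_scree`, or any data frame with columns `rank`
#'   and `mean_distance`.
#' @param refine Refine the integer grid optimum by golden-section search
#'   (default `TRUE`); turn off to keep the pure grid estimate.
#' @return A `segmented_fit` list: `slope1`, `slope2`, `intercept`,
#'   `change_point`, `slope_se`, `slope_ci`, `slope_p`,
#'   `changepoint_ci` (filled by [bootstrap_changepoint_ci()]), `rss`,
#'   `rss_linear`, `n`, `degenerate`, and the data (`x`, `y`).
#' @export
fit_segmented <- function(series, refine = TRUE) {
  df <- as.data.frame(series)
  if (!all(c("rank", "mean_distance") %in% names(df))) {
    abort("`series` needs columns `rank` and `mean_distance`.")
  }
  x <- as.numeric(df$rank); y <- as.numeric(df$mean_distance)
  n <- length(x)
  if (n < 10) abort("Segmented fit needs a series of length >= 10.")

  lin <- lm(y ~ x)
  rss_linear <- sum(lin$residuals^2)

  if (sd(y) == 0) {
    out <- list(slope1 = 0, slope2 = 0, intercept = y[1], change_point = NA_real_,
                slope_se = c(NA_real_, NA_real_),
                slope_ci = matrix(NA_real_, 2, 2,
                                  dimnames = list(c("slope1", "slope2"),
                                                  c("lower", "upper"))),
                slope_p = c(NA_real_, NA_real_), changepoint_ci = NULL,
                rss = 0, rss_linear = rss_linear, n = n,
                degenerate = TRUE, x = x, y = y)
    class(out) <- "segmented_fit"
    return(out)
  }

  prof <- fit_segmented_xy(x, y, refine = refine)
  psi <- prof$psi
  h <- pmax(0, x - psi)
  mod <- lm(y ~ x + h)
  cf <- coef(mod)
  vc <- suppressWarnings(vcov(mod))  # noiseless series fit is legitimate
  slope1 <- unname(cf["x"])
  slope2 <- unname(cf["x"] + cf["h"])
  se1 <- sqrt(vc["x", "x"])
  se2 <- sqrt(vc["x", "x"] + vc["h", "h"] + 2 * vc["x", "h"])
  dfree <- mod$df.residual
  tcrit <- qt(0.975, dfree)
  tval <- c(slope1 / se1, slope2 / se2)
  out <- list(
    slope1 = slope1, slope2 = slope2, intercept = unname(cf["(Intercept)"]),
    change_point = psi,
    slope_se = c(se1, se2),
    slope_ci = matrix(c(slope1 - tcrit * se1, slope2 - tcrit * se2,
                        slope1 + tcrit * se1, slope2 + tcrit * se2),
                      2, 2, dimnames = list(c("slope1", "slope2"),
                                            c("lower", "upper"))),
    slope_p = 2 * pt(abs(tval), dfree, lower.tail = FALSE),
    changepoint_ci = NULL,
    rss = sum(mod$residuals^2), rss_linear = rss_linear, n = n,
    degenerate = FALSE, x = x, y = y)
  class(out) <- "segmented_fit"
  out
}

#' @export
print.segmented_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<segmented_fit> degenerate series: no change-point\n")
    return(invisible(x))
  }
  cat("<segmented_fit> n = ", x$n,
      "\n  change-point  ", format(x$change_point, digits = 6),
      "\n  slope1        ", format(x$slope1, digits = 4),
      " (p = ", format.pval(x$slope_p[1], digits = 3), ")",
      "\n  slope2        ", format(x$slope2, digits = 4),
      " (p = ", format.pval(x$slope_p[2], digits = 3), ")",
      "\n  slope ratio   ", format(slope_ratio(x), digits = 4),
      "\n  RSS ", format(x$rss, digits = 6),
      " (single line ", format(x$rss_linear, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Fitted values of a segmented fit
#'
#' @param object A `segmented_fit`.
#' @param newdata Optional numeric vector of ranks (defaults to the
#'   fitted series).
#' @param ... Unused.
#' @return Numeric vector of fitted mean distances; continuous at the
#'   change-point by construction.
#' @export
predict.segmented_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$x
  if (object$degenerate) return(rep(object$intercept, length(x)))
  object$intercept + object$slope1 * x +
    (object$slope2 - object$slope1) * pmax(0, x - object$change_point)
}

#' Ratio of the two segment slopes
#'
#' `slope2 / slope1`: how many times faster structural divergence grows
#' past the change-point than before it.
#'
#' @param fit A `segmented_fit`.
#' @return A single number.
#' @export
slope_ratio <- function(fit) {
  if (fit$degenerate) abort("Degenerate fit has no slopes.")
  if (fit$slope1 == 0) abort("slope1 is zero; ratio undefined.")
  fit$slope2 / fit$slope1
}

#' Bootstrap percentile interval for the change-point
#'
#' Case-resamples the (rank, distance) pairs, refits the broken stick on
#' each resample, and returns the percentile interval of the estimated
#' change-point. Reproducible under a fixed seed.
#'
#' @param series As in [fit_segmented()].
#' @param B Number of bootstrap resamples (>= 200).
#' @param seed Optional integer seed.
#' @param level Confidence level (default 0.95).
#' @return Length-2 vector (lower, upper) with attribute `psi_boot`
#'   holding the bootstrap draws.
#' @export
bootstrap_changepoint_ci <- function(series, B = 500, seed = NULL,
                                     level = 0.95) {
  if (B < 200) abort("`B` must be at least 200.")
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(series)
  x <- as.numeric(df$rank); y <- as.numeric(df$mean_distance)
  n <- length(x)
  psi_b <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_segmented_xy(x[idx], y[idx], refine = TRUE)$psi
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(quantile(psi_b, c(alpha, 1 - alpha), type = 7))
  attr(ci, "psi_boot") <- psi_b
  ci
}

#' Permutation test for the existence of a change-point
#'
#' The conditional-on-`psi` slope p-values overstate evidence for a break
#' because `psi` itself was estimated. This companion test uses the RSS
#' improvement of the segmented over the single-line fit as statistic and
#' builds its null by permuting the single-line residuals (a Davies-type
#' adjustment for the unidentified nuisance parameter).
#'
#' @param series As in [fit_segmented()].
#' @param n_perm Number of permutations (default 199).
#' @param seed Optional integer seed.
#' @return A list with `statistic` (RSS improvement) and `p_value`.
#' @export
segmented_permutation_test <- function(series, n_perm = 199, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(series)
  x <- as.numeric(df$rank); y <- as.numeric(df$mean_distance)
  lin <- lm(y ~ x)
  fit0 <- fit_segmented_xy(x, y, refine = FALSE)
  obs <- sum(lin$residuals^2) - fit0$rss
  res <- lin$residuals; fv <- lin$fitted.values
  null_stats <- vapply(seq_len(n_perm), function(b) {
    yb <- fv + sample(res)
    linb <- sum(lm(yb ~ x)$residuals^2)
    linb - fit_segmented_xy(x, yb, refine = FALSE)$rss
  }, numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(null_stats >= obs)) / (n_perm + 1))
}

#' @method tidy segmented_fit
#' @export
tidy.segmented_fit <- function(x, ...) {
  tibble(term = c("slope1", "slope2"),
         estimate = c(x$slope1, x$slope2),
         std.error = x$slope_se,
         p.value = x$slope_p,
         conf.low = x$slope_ci[, "lower"],
         conf.high = x$slope_ci[, "upper"])
}

#' @method glance segmented_fit
#' @export
glance.segmented_fit <- function(x, ...) {
  tibble(change_point = x$change_point,
         changepoint_ci_lower = if (is.null(x$changepoint_ci)) NA_real_
                                else x$changepoint_ci[1],
         changepoint_ci_upper = if (is.null(x$changepoint_ci)) NA_real_
                                else x$changepoint_ci[2],
         slope1 = x$slope1, slope2 = x$slope2,
         slope_ratio = if (x$degenerate || x$slope1 == 0) NA_real_
                       else x$slope2 / x$slope1,
         rss = x$rss, rss_linear = x$rss_linear,
         n = x$n, degenerate = x$degenerate)
}
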