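#' Pearson chi-square for a 2x2 table
#'
#' The uncorrected Pearson statistic
#' `N * (ad - bc)^2 / (r1 * r2 * c1 * c2)` with a p-value from the
#' chi-square distribution on 1 degree of freedom. No continuity
#' correction is applied.
#'
#' @param a,b,c,d Cell counts, row-wise: the table is
#'   `rbind(c(a, b), c(c, d))`. Alternatively pass a 2x2 matrix as `a`.
#' @return A list with `chi2` and `p_value`.
#' @export
#' @examples
#' pearson_chi2(853, 110, 116, 61)$chi2  # 62.25 to printed precision
pearson_chi2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (any(dim(a) != 2)) abort("`a` must be a 2x2 matrix.")
    tab <- a
  } else {
    tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("Counts must be non-negative integers.")
  }
  r <- rowSums(tab); cl <- colSums(tab)
  if (any(r == 0) || any(cl == 0)) {
    abort("Chi-square statistic undefined: a table marginal is zero.")
  }
  n <- sum(tab)
  chi2 <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (r[1] * r[2] * cl[1] * cl[2])
  list(chi2 = unname(chi2),
       p_value = unname(pchisq(chi2, df = 1, lower.tail = FALSE)))
}

#' Segment-enrichment test from presence/absence counts
#'
#' Takes a per-variable 2x2 count table (as produced by
#' [membership_counts()], or transcribed from a published analysis) and
#' tests each variable for over- or under-representation in the
#' high-variability segment. Each variable is then assigned one of three
#' behavioural patterns:
#'
#' * **1 — random**: no significant segment differentiation
#'   (`p >= alpha`); the variable's occurrence between segments is
#'   indistinguishable from chance.
#' * **2 — segment-1 predominant**: significant, with fewer segment-2
#'   appearances than expected under independence; a stable background
#'   characteristic.
#' * **3 — segment-2 overrepresented**: significant, with more segment-2
#'   appearances than expected; a disease-active structural signal.
#'
#' @param counts Tibble with columns `variable`, `absence_seg1`,
#'   `presence_seg1`, `absence_seg2`, `presence_seg2`.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` (default) mirrors the uncorrected
#'   convention of the published analysis.
#' @return An `ms_enrichment` tibble sorted by descending `chi2`, with
#'   columns `variable`, the four counts, `expected_presence_seg2`,
#'   `chi2`, `p_value`, `pattern`.
#' @export
enrich_counts <- function(counts, alpha = 0.05, p_adjust = "none") {
  counts <- as_tibble(counts)
  needed <- c("variable", "absence_seg1", "presence_seg1",
              "absence_seg2", "presence_seg2")
  if (!all(needed %in% names(counts))) {
    abort(paste0("`counts` must have columns: ", paste(needed, collapse = ", ")))
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  n_total <- with(counts, absence_seg1[1] + presence_seg1[1] +
                    absence_seg2[1] + presence_seg2[1])
  seg2 <- with(counts, absence_seg2[1] + presence_seg2[1])
  tests <- purrr::map2(
    purrr::map2(counts$absence_seg1, counts$presence_seg1, c),
    purrr::map2(counts$absence_seg2, counts$presence_seg2, c),
    function(r1, r2) pearson_chi2(rbind(r1, r2)))
  out <- counts |>
    dplyr::mutate(
      expected_presence_seg2 =
        (.data$presence_seg1 + .data$presence_seg2) * seg2 / n_total,
      chi2 = purrr::map_dbl(tests, "chi2"),
      p_value = stats::p.adjust(purrr::map_dbl(tests, "p_value"),
                                method = p_adjust),
      pattern = dplyr::case_when(
        .data$p_value >= alpha ~ 1L,
        .data$presence_seg2 > .data$expected_presence_seg2 ~ 3L,
        .default = 2L)) |>
    dplyr::arrange(dplyr::desc(.data$chi2))
  structure(out, class = c("ms_enrichment", class(as_tibble(out))),
            alpha = alpha, p_adjust = p_adjust)
}

#' Segment-enrichment classification of variables from a fitted scree
#'
#' Splits the ranked triad series at `floor(change_point)` (ranks up to
#' and including the floor form segment 1), counts each variable's
#' presence on either side, and runs [enrich_counts()].
#'
#' @param series An `ms_scree` from [scan_triads()].
#' @param fit A `segmented_fit` from [fit_segmented()] on that series.
#' @inheritParams enrich_counts
#' @return An `ms_enrichment` tibble; see [enrich_counts()].
#' @export
segment_enrichment <- function(series, fit, alpha = 0.05, p_adjust = "none") {
  if (inherits(fit, "segmented_fit") && fit$degenerate) {
    abort("Degenerate segmented fit: no change-point to split on.")
  }
  split_rank <- floor(if (inherits(fit, "segmented_fit")) fit$change_point
                      else as.numeric(fit))
  enrich_counts(membership_counts(series, split_rank),
                alpha = alpha, p_adjust = p_adjust)
}

#' Partition variables into the three behavioural pattern classes
#'
#' @param rows An `ms_enrichment` tibble.
#' @return An `ms_patterns` list with elements `random`
#'   (pattern 1), `segment1_predominant` (pattern 2) and
#'   `segment2_overrepresented` (pattern 3), each a character vector in
#'   descending chi-square order. Every variable lands in exactly one
#'   class.
#' @export
classify_patterns <- function(rows) {
  rows <- dplyr::arrange(as_tibble(rows), dplyr::desc(.data$chi2))
  out <- list(
    random = rows$variable[rows$pattern == 1L],
    segment1_predominant = rows$variable[rows$pattern == 2L],
    segment2_overrepresented = rows$variable[rows$pattern == 3L])
  structure(out, class = "ms_patterns")
}

#' @export
print.ms_patterns <- function(x, ...) {
  lab <- c(random = "Pattern 1 (random, no segment differentiation)",
           segment1_predominant = "Pattern 2 (low-variability segment predominant)",
           segment2_overrepresented = "Pattern 3 (high-variability segment overrepresented)")
  for (k in names(lab)) {
    cat(lab[[k]], ":\n  ",
        if (length(x[[k]])) paste(x[[k]], collapse = ", ") else "(none)",
        "\n", sep = "")
  }
  invisible(x)
}
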