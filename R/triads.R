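#' Enumerate all unordered variable triads
#'
#' All `choose(p, 3)` combinations without repetition, each tuple sorted
#' and the list in deterministic lexicographic order (C-locale radix
#' sort), so a 20-variable panel yields 1,140 triads and each variable
#' appears in `choose(p - 1, 2)` of them.
#'
#' @param variable_names Character vector of at least 3 unique names.
#' @return A tibble with columns `var1`, `var2`, `var3`.
#' @export
#' @examples
#' nrow(enumerate_triads(letters[1:20]))  # 1140
enumerate_triads <- function(variable_names) {
  if (length(variable_names) < 3) abort("Need at least 3 variables.")
  if (anyDuplicated(variable_names)) abort("Variable names must be unique.")
  nm <- sort(variable_names, method = "radix")
  cmb <- combn(nm, 3)
  tibble(var1 = cmb[1, ], var2 = cmb[2, ], var3 = cmb[3, ])
}

#' Score every triad and build the ranked scree series
#'
#' Computes each triad's mean Marczewski-Steinhaus distance over all
#' patient pairs and ranks triads ascending (rank 1 = most structurally
#' cohesive). The `C(n, 2)` per-variable pair distances are computed once
#' and reused across the `C(p-1, 2)` triads containing each variable, so
#' the full 20-variable, 366-patient scan is a matter of seconds. Ties
#' are broken by lexicographic triad order (stable sort).
#'
#' @param cohort An `ms_cohort`.
#' @inheritParams triad_distance
#' @return An `ms_scree` tibble with columns `rank`, `var1`, `var2`,
#'   `var3`, `mean_distance`, plus attributes `mode`, `n_patients`,
#'   `n_variables`.
#' @export
scan_triads <- function(cohort, mode = c("mean-per-variable", "soergel")) {
  mode <- match.arg(mode)
  vars <- cohort_variables(cohort)
  triads <- enumerate_triads(vars)
  ps <- pair_stats(cohort, variables = sort(vars, method = "radix"))
  cols <- colnames(ps$ratio)
  i1 <- match(triads$var1, cols)
  i2 <- match(triads$var2, cols)
  i3 <- match(triads$var3, cols)

  if (mode == "mean-per-variable" && !anyNA(ps$ratio)) {
    # mean over pairs of the per-variable average = average of the three
    # per-variable mean pair distances
    mv <- colMeans(ps$ratio)
    md <- (mv[i1] + mv[i2] + mv[i3]) / 3
  } else if (mode == "mean-per-variable") {
    md <- vapply(seq_len(nrow(triads)), function(k) {
      mean(rowMeans(ps$ratio[, c(i1[k], i2[k], i3[k])], na.rm = TRUE),
           na.rm = TRUE)
    }, numeric(1))
  } else {
    md <- vapply(seq_len(nrow(triads)), function(k) {
      num <- rowSums(ps$absdiff[, c(i1[k], i2[k], i3[k])], na.rm = TRUE)
      den <- rowSums(ps$pairmax[, c(i1[k], i2[k], i3[k])], na.rm = TRUE)
      d <- num / den
      d[den == 0] <- 0
      mean(d)
    }, numeric(1))
  }

  ord <- order(md)  # stable: ties keep lexicographic triad order
  out <- triads[ord, ]
  out$mean_distance <- unname(md[ord])
  out$rank <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "rank")
  structure(out,
            class = c("ms_scree", class(as_tibble(out))),
            mode = mode, n_patients = nrow(cohort),
            n_variables = length(vars))
}

#' @export
print.ms_scree <- function(x, ...) {
  cat("<ms_scree> ", nrow(x), " triads over ", attr(x, "n_variables"),
      " variables (", attr(x, "n_patients"), " patients, mode ",
      attr(x, "mode"), ")\n", sep = "")
  NextMethod()
}

#' Per-variable presence/absence counts across the two scree segments
#'
#' Splits the ranked series after `split_rank` and, for each variable,
#' counts the triads in which it is present or absent on either side.
#' For a p-variable panel each variable is present in `choose(p-1, 2)`
#' triads and absent from the remaining `choose(p, 3) - choose(p-1, 2)`
#' (171 and 969 for p = 20).
#'
#' @param series An `ms_scree` (or a data frame with `rank`, `var1`,
#'   `var2`, `var3`).
#' @param split_rank Last rank belonging to segment 1
#'   (`1 <= split_rank < nrow(series)`).
#' @return A tibble with columns `variable`, `absence_seg1`,
#'   `presence_seg1`, `absence_seg2`, `presence_seg2`, one row per
#'   variable in lexicographic order.
#' @export
membership_counts <- function(series, split_rank) {
  n_triads <- nrow(series)
  if (split_rank < 1 || split_rank >= n_triads) {
    abort("`split_rank` must satisfy 1 <= split_rank < number of triads.")
  }
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(series), "rank", "var1", "var2", "var3"),
    cols = c("var1", "var2", "var3"), values_to = "variable")
  vars <- sort(unique(long$variable), method = "radix")
  seg1 <- split_rank
  seg2 <- n_triads - split_rank
  long |>
    dplyr::mutate(segment = ifelse(.data$rank <= split_rank, 1L, 2L)) |>
    dplyr::count(.data$variable, .data$segment) |>
    tidyr::complete(variable = vars, segment = 1:2, fill = list(n = 0L)) |>
    tidyr::pivot_wider(names_from = "segment", values_from = "n",
                       names_prefix = "presence_seg") |>
    dplyr::mutate(absence_seg1 = seg1 - .data$presence_seg1,
                  absence_seg2 = seg2 - .data$presence_seg2) |>
    dplyr::select("variable", "absence_seg1", "presence_seg1",
                  "absence_seg2", "presence_seg2") |>
    dplyr::arrange(.data$variable)
}
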