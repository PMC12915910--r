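#' Marczewski-Steinhaus distance between two non-negative scalars
#'
#' `|a - b| / max(a, b)`, the scalar form of the set-theoretic
#' Marczewski-Steinhaus dissimilarity. Lies in \[0, 1\]; both values zero
#' give distance 0 (no dissimilarity, the limit consistent with the
#' metric axioms). Vectorised over `a` and `b`.
#'
#' @param a,b Non-negative numeric vectors (recycled).
#' @return Numeric vector of distances in \[0, 1\].
#' @export
#' @examples
#' ms_scalar(2, 8)   # 0.75
#' ms_scalar(0, 7)   # 1
ms_scalar <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    abort("Marczewski-Steinhaus distance requires non-negative values.")
  }
  mx <- pmax(a, b)
  d <- abs(a - b) / mx
  d[!is.na(mx) & mx == 0] <- 0
  d
}

#' Marczewski-Steinhaus distance between two 3-variable patient profiles
#'
#' The scalar formula extends to a triad of variables in two selectable
#' ways. `"mean-per-variable"` (the default) applies [ms_scalar()] to each
#' variable and averages the three values. `"soergel"` is the
#' set-theoretic generalisation `sum(|x_i - y_i|) / sum(max(x_i, y_i))`
#' (Soergel/Ruzicka distance), 0 when both profiles are all-zero. Both
#' are metrics on non-negative data with range \[0, 1\]. Coordinates where
#' either profile is `NA` are dropped and the distance renormalised over
#' the observed variables.
#'
#' @param x,y Non-negative numeric vectors of length 3.
#' @param mode `"mean-per-variable"` or `"soergel"`.
#' @return A single distance in \[0, 1\].
#' @export
#' @examples
#' triad_distance(c(2, 4, 10), c(8, 4, 5))              # (0.75 + 0 + 0.5)/3
#' triad_distance(c(1, 0, 0), c(0, 1, 0), "soergel")    # 1
triad_distance <- function(x, y, mode = c("mean-per-variable", "soergel")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  if (!any(keep)) return(NA_real_)
  x <- x[keep]; y <- y[keep]
  if (mode == "mean-per-variable") {
    mean(ms_scalar(x, y))
  } else {
    if (any(x < 0) || any(y < 0)) {
      abort("Marczewski-Steinhaus distance requires non-negative values.")
    }
    den <- sum(pmax(x, y))
    if (den == 0) 0 else sum(abs(x - y)) / den
  }
}

# Lower-triangle pair index order used throughout (matches stats::dist):
# (2,1), (3,1), ..., (n,1), (3,2), ...
pair_index <- function(n) {
  j <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  list(i = i, j = j)
}

# Per-variable pair statistics over all C(n,2) patient pairs:
# ratio (M-S scalar distance), absdiff and pairmax (Soergel components).
# NA in either member of a pair propagates as NA for that variable.
pair_stats <- function(cohort, variables = NULL) {
  m <- cohort_values(cohort)
  if (!is.null(variables)) m <- m[, variables, drop = FALSE]
  if (any(m < 0, na.rm = TRUE)) {
    abort("Marczewski-Steinhaus distance requires non-negative values.")
  }
  n <- nrow(m)
  idx <- pair_index(n)
  a <- m[idx$i, , drop = FALSE]
  b <- m[idx$j, , drop = FALSE]
  pairmax <- pmax(a, b)
  absdiff <- abs(a - b)
  ratio <- absdiff / pairmax
  ratio[!is.na(pairmax) & pairmax == 0] <- 0
  list(ratio = ratio, absdiff = absdiff, pairmax = pairmax,
       n = n, i = idx$i, j = idx$j)
}

# Pair-distance vector for one triad from precomputed pair statistics.
triad_pair_distances <- function(ps, cols, mode) {
  if (mode == "mean-per-variable") {
    rowMeans(ps$ratio[, cols, drop = FALSE], na.rm = TRUE)
  } else {
    num <- rowSums(ps$absdiff[, cols, drop = FALSE], na.rm = TRUE)
    den <- rowSums(ps$pairmax[, cols, drop = FALSE], na.rm = TRUE)
    d <- num / den
    d[den == 0] <- 0
    d
  }
}

#' Patient-by-patient distance matrix for one variable triad
#'
#' Computes the symmetric matrix of Marczewski-Steinhaus distances between
#' all patient pairs, restricted to the three named variables. Under the
#' cohort's `"pairwise"` missing policy a missing variable is dropped from
#' the affected pair and the distance renormalised over the observed ones.
#'
#' @param cohort An `ms_cohort`.
#' @param triad Character vector of 3 variable names.
#' @inheritParams triad_distance
#' @return An `ms_distmat`: the distance matrix with attributes `triad`
#'   and `mode`, patient ids as dimnames.
#' @export
distance_matrix <- function(cohort, triad,
                            mode = c("mean-per-variable", "soergel")) {
  mode <- match.arg(mode)
  if (length(triad) != 3) abort("`triad` must name exactly 3 variables.")
  missing_vars <- setdiff(triad, cohort_variables(cohort))
  if (length(missing_vars)) {
    abort(paste0("Unknown variable(s): ", paste(missing_vars, collapse = ", ")))
  }
  ps <- pair_stats(cohort, variables = triad)
  d <- triad_pair_distances(ps, seq_len(3), mode)
  n <- ps$n
  out <- matrix(0, n, n, dimnames = list(cohort$patient_id, cohort$patient_id))
  out[cbind(ps$i, ps$j)] <- d
  out[cbind(ps$j, ps$i)] <- d
  structure(out, triad = sort(triad), mode = mode,
            class = c("ms_distmat", "matrix", "array"))
}

#' Mean of a distance matrix's strict upper triangle
#'
#' The per-triad summary statistic of the screening pipeline: the average
#' dissimilarity over all unordered patient pairs.
#'
#' @param m A square symmetric matrix (e.g. an `ms_distmat`).
#' @return A single number.
#' @export
mean_distance <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2) {
    abort("`m` must be a square matrix over at least 2 patients.")
  }
  mean(m[upper.tri(m)])
}

#' Hierarchical patient tree from a distance matrix
#'
#' Agglomerative clustering of patients; `"single"` linkage (nearest
#' neighbour) is the default, with average and complete linkage available
#' for sensitivity analysis. Delegates to [stats::hclust()].
#'
#' @param m An `ms_distmat` (or any symmetric distance matrix with
#'   dimnames).
#' @param linkage `"single"`, `"average"` or `"complete"`.
#' @return An object of class `hclust`.
#' @export
single_linkage_tree <- function(m, linkage = c("single", "average", "complete")) {
  linkage <- match.arg(linkage)
  hclust(as.dist(unclass(m)), method = linkage)
}

quote_newick_label <- function(x) {
  reserved <- grepl("[][(),:;'\"[:space:]]", x)
  x[reserved] <- paste0("'", gsub("'", "''", x[reserved]), "'")
  x
}

#' Serialise a patient tree to Newick
#'
#' Branch lengths are differences of merge heights: leaves sit at height
#' 0 and each child branch spans from its own merge height up to its
#' parent's, so the tree depth equals the root merge height. Labels
#' containing Newick-reserved characters are quoted.
#'
#' @param tree An `hclust` object.
#' @param digits Significant digits for branch lengths (default 10).
#' @return A single Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "hclust"))
  labels <- quote_newick_label(tree$labels)
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  node_str <- function(k) {
    # k < 0: leaf -k; k > 0: internal node k. Returns c(string, height).
    if (k < 0) return(list(s = labels[-k], h = 0))
    left <- node_str(tree$merge[k, 1])
    right <- node_str(tree$merge[k, 2])
    h <- tree$height[k]
    list(s = paste0("(", left$s, ":", fmt(h - left$h), ",",
                    right$s, ":", fmt(h - right$h), ")"),
         h = h)
  }
  paste0(node_str(nrow(tree$merge))$s, ";")
}
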