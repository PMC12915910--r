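# Independent brute-force oracles. These re-derive expected values from
# first principles with plain loops, never through the package's own
# computational path.

# Scalar M-S distance straight from the formula.
oracle_ms <- function(a, b) {
  if (a == 0 && b == 0) return(0)
  abs(a - b) / max(a, b)
}

# Triad distance by explicit per-variable arithmetic.
oracle_triad <- function(x, y, mode) {
  if (mode == "mean-per-variable") {
    mean(vapply(1:3, function(k) oracle_ms(x[k], y[k]), numeric(1)))
  } else {
    den <- sum(pmax(x, y))
    if (den == 0) 0 else sum(abs(x - y)) / den
  }
}

# Full patient-pair distance matrix by double loop.
oracle_distance_matrix <- function(values, mode) {
  n <- nrow(values)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) out[i, j] <- oracle_triad(values[i, ], values[j, ], mode)
    }
  }
  out
}

# Mean distance of every triad by recomputing each matrix from scratch.
oracle_scan <- function(values, mode) {
  vars <- sort(colnames(values), method = "radix")
  combos <- combn(vars, 3)
  md <- apply(combos, 2, function(tri) {
    m <- oracle_distance_matrix(values[, tri, drop = FALSE], mode)
    mean(m[upper.tri(m)])
  })
  data.frame(var1 = combos[1, ], var2 = combos[2, ], var3 = combos[3, ],
             mean_distance = md)
}

# Naive O(n^3) single-linkage agglomeration; returns sorted merge heights.
oracle_single_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a < b) {
          dd <- min(d[clusters[[a]], clusters[[b]]])
          if (dd < bestd) { bestd <- dd; best <- c(a, b) }
        }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Exhaustive broken-stick profile: lm at every integer psi in [5, n-5].
oracle_segmented <- function(x, y) {
  best <- list(psi = NA, rss = Inf)
  xs <- sort(x)
  n <- length(x)
  for (psi in seq(ceiling(xs[5]), ceiling(xs[n - 4]) - 1)) {
    h <- pmax(0, x - psi)
    rss <- sum(lm(y ~ x + h)$residuals^2)
    if (rss < best$rss) best <- list(psi = psi, rss = rss)
  }
  best
}

# Chi-square via expected counts, sum((O - E)^2 / E).
oracle_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Harrell's C by explicit pair loop.
oracle_harrell <- function(time, event, score) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (score[i] > score[j]) num <- num + 1
        else if (score[i] == score[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# Per-variable segment membership counts by exhaustive enumeration.
oracle_membership <- function(series, split_rank) {
  vars <- sort(unique(c(series$var1, series$var2, series$var3)),
               method = "radix")
  out <- data.frame(variable = vars, absence_seg1 = 0, presence_seg1 = 0,
                    absence_seg2 = 0, presence_seg2 = 0)
  for (r in seq_len(nrow(series))) {
    tri <- c(series$var1[r], series$var2[r], series$var3[r])
    seg <- if (series$rank[r] <= split_rank) "seg1" else "seg2"
    for (v in vars) {
      col <- paste0(if (v %in% tri) "presence_" else "absence_", seg)
      out[out$variable == v, col] <- out[out$variable == v, col] + 1
    }
  }
  out
}
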