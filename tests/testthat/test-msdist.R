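test_that("scalar distance follows the ratio formula", {
  expect_equal(ms_scalar(5, 5), 0)
  expect_equal(ms_scalar(0, 7), 1)
  expect_equal(ms_scalar(2, 8), 0.75)
  expect_equal(ms_scalar(0, 0), 0)       # limit convention
  expect_error(ms_scalar(-1, 2), "non-negative")
})

test_that("triad distance matches hand arithmetic in both modes", {
  expect_equal(triad_distance(c(2, 4, 10), c(8, 4, 5), "mean-per-variable"),
               (0.75 + 0 + 0.5) / 3)
  expect_equal(triad_distance(c(1, 0, 0), c(0, 1, 0), "soergel"), 1)
  x <- c(3, 1, 4)
  expect_equal(triad_distance(x, x, "mean-per-variable"), 0)
  expect_equal(triad_distance(x, x, "soergel"), 0)
  expect_equal(triad_distance(c(0, 0, 0), c(0, 0, 0), "soergel"), 0)
})

test_that("metric properties hold on 1e4 random non-negative triples", {
  set.seed(99)
  n_checks <- 1e4
  for (mode in c("mean-per-variable", "soergel")) {
    x <- matrix(rexp(3 * n_checks), ncol = 3)
    y <- matrix(rexp(3 * n_checks), ncol = 3)
    z <- matrix(rexp(3 * n_checks), ncol = 3)
    # sprinkle exact zeros to exercise the 0/0 convention
    x[sample(length(x), 500)] <- 0
    y[sample(length(y), 500)] <- 0
    dxy <- dyx <- dxz <- dzy <- dxx <- numeric(n_checks)
    for (i in seq_len(n_checks)) {
      dxy[i] <- triad_distance(x[i, ], y[i, ], mode)
      dyx[i] <- triad_distance(y[i, ], x[i, ], mode)
      dxz[i] <- triad_distance(x[i, ], z[i, ], mode)
      dzy[i] <- triad_distance(z[i, ], y[i, ], mode)
      dxx[i] <- triad_distance(x[i, ], x[i, ], mode)
    }
    expect_equal(dxy, dyx)                                  # symmetry
    expect_true(all(dxy >= 0 & dxy <= 1))                   # range
    expect_true(all(dxx == 0))                              # identity
    expect_true(all(dxy <= dxz + dzy + 1e-12))              # triangle
  }
})

test_that("rescaling invariances hold for each mode", {
  co <- toy_cohort(n = 12, p = 4, seed = 7)
  # mean-per-variable: invariant to rescaling any single column, because
  # each per-variable ratio |a-b|/max(a,b) is scale-free on its own
  base <- distance_matrix(co, c("v1", "v2", "v3"), "mean-per-variable")
  scaled_df <- as.data.frame(mstriad:::cohort_values(co))
  scaled_df$v2 <- scaled_df$v2 * 37.5
  co2 <- as_cohort(scaled_df)
  rescaled <- distance_matrix(co2, c("v1", "v2", "v3"), "mean-per-variable")
  expect_equal(unclass(base), unclass(rescaled),
               ignore_attr = TRUE, tolerance = 1e-12)

  # soergel couples the coordinates through shared sums, so only a common
  # rescaling of the whole profile leaves it unchanged
  base_s <- distance_matrix(co, c("v1", "v2", "v3"), "soergel")
  all_df <- as.data.frame(mstriad:::cohort_values(co) * 37.5)
  all_s <- distance_matrix(as_cohort(all_df), c("v1", "v2", "v3"), "soergel")
  expect_equal(unclass(base_s), unclass(all_s),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("distance matrices equal the brute-force double loop", {
  co <- toy_cohort(n = 20, p = 5, seed = 13)
  vals <- mstriad:::cohort_values(co)
  for (mode in c("mean-per-variable", "soergel")) {
    dm <- distance_matrix(co, c("v1", "v3", "v5"), mode)
    oracle <- oracle_distance_matrix(vals[, c("v1", "v3", "v5")], mode)
    expect_equal(unclass(dm), oracle, ignore_attr = TRUE, tolerance = 1e-12)
    expect_true(isSymmetric(unclass(dm)))
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm >= 0 & dm <= 1))
  }
  expect_error(distance_matrix(co, c("v1", "v2", "nope")), "Unknown variable")
})

test_that("distance matrix examples forced by the scalar formula", {
  df <- data.frame(a = c(2, 8, 8, 8), b = c(1, 1, 1, 1), c = c(3, 3, 3, 3))
  co <- as_cohort(df)
  dm <- distance_matrix(co, c("a", "b", "c"), "mean-per-variable")
  expect_equal(dm[1, 2], 0.25)   # only 'a' differs: 0.75/3
  expect_equal(dm[1, 3], 0.25)
  expect_equal(dm[2, 3], 0)
})

test_that("mean_distance averages the strict upper triangle", {
  z <- matrix(0, 3, 3)
  expect_equal(mean_distance(z), 0)
  m2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(mean_distance(m2), 0.5)
  set.seed(2)
  v <- runif(6)
  m4 <- matrix(0, 4, 4)
  m4[upper.tri(m4)] <- v
  m4 <- m4 + t(m4)
  expect_equal(mean_distance(m4), sum(v) / 6)
  expect_error(mean_distance(matrix(0, 1, 1)), "at least 2")
})

test_that("pairwise missing policy renormalises over observed variables", {
  df <- data.frame(a = c(2, 8, 1, 1), b = c(4, NA, 2, 2), c = c(10, 5, 3, 3))
  co <- as_cohort(df, missing = "pairwise")
  dm <- distance_matrix(co, c("a", "b", "c"), "mean-per-variable")
  # pair (1,2): b missing -> mean over a and c only
  expect_equal(dm[1, 2], (0.75 + 0.5) / 2)
  # pair (1,3): all observed
  expect_equal(dm[1, 3], mean(c(0.5, 0.5, 0.7)))
  expect_error(as_cohort(df), "Missing value")
})

test_that("single linkage matches a naive agglomeration oracle", {
  d3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
               dimnames = list(paste0("P", 1:3), paste0("P", 1:3)))
  tree <- single_linkage_tree(d3)
  expect_equal(tree$height, c(0.1, 0.9))

  co <- toy_cohort(n = 15, p = 4, seed = 21)
  dm <- distance_matrix(co, c("v1", "v2", "v4"))
  tree15 <- single_linkage_tree(dm)
  expect_equal(sort(tree15$height),
               sort(oracle_single_linkage_heights(unclass(dm))),
               tolerance = 1e-12)
  # ultrametric: merge heights non-decreasing root-ward
  expect_true(all(diff(tree15$height) >= 0))
})

test_that("newick export terminates, quotes labels, and encodes heights", {
  # two patients at distance d -> single merge at height d
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("A", "B (x)"), c("A", "B (x)")))
  t2 <- single_linkage_tree(d2)
  expect_equal(t2$height, 0.3)
  nwk2 <- to_newick(t2)
  expect_match(nwk2, ";$")
  expect_match(nwk2, "'B \\(x\\)'")  # reserved chars quoted
})

test_that("newick export round-trips through an independent parser", {
  skip_if_not_installed("ape")
  co <- toy_cohort(n = 8, p = 3, seed = 5)
  dm <- distance_matrix(co, c("v1", "v2", "v3"))
  tree <- single_linkage_tree(dm)
  nwk <- to_newick(tree)
  expect_match(nwk, ";$")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, co$patient_id)
  # leaf depths all equal the root height (ultrametric with height diffs)
  depths <- ape::node.depth.edgelength(phy)[seq_len(8)]
  expect_equal(max(abs(depths - max(tree$height))), 0, tolerance = 1e-9)
})
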