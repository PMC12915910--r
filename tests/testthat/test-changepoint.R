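test_that("noiseless two-slope series is recovered almost exactly", {
  x <- 1:1000
  y <- broken_stick_y(x, 0.0002, 0.001, 500)
  fit <- fit_segmented(scree_tbl(x, y))
  expect_lt(abs(fit$change_point - 500), 1)
  expect_equal(fit$slope1, 0.0002, tolerance = 1e-6)
  expect_equal(fit$slope2, 0.001, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-18)
})

test_that("grid profile equals the exhaustive per-rank oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(50:200, 1)
    x <- 1:n
    y <- broken_stick_y(x, 0.0005, 0.002, psi = round(n * 0.7),
                        noise_sd = 0.01)
    fit <- fit_segmented(scree_tbl(x, y), refine = FALSE)
    oracle <- oracle_segmented(x, y)
    expect_equal(fit$change_point, oracle$psi)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-10)
  }
})

test_that("refinement only lowers the RSS and keeps continuity", {
  set.seed(10)
  x <- 1:300
  y <- broken_stick_y(x, 1e-4, 9e-4, 201.4, noise_sd = 0.004)
  grid_fit <- fit_segmented(scree_tbl(x, y), refine = FALSE)
  fit <- fit_segmented(scree_tbl(x, y))
  expect_lte(fit$rss, grid_fit$rss)
  expect_lte(fit$rss, fit$rss_linear)
  # fitted function continuous at the change-point
  eps <- 1e-12
  left <- predict(fit, fit$change_point - eps)
  right <- predict(fit, fit$change_point + eps)
  expect_lt(abs(left - right), 1e-12)
  # conditional inference present
  expect_true(all(is.finite(fit$slope_se)))
  expect_true(all(fit$slope_ci[, "lower"] < fit$slope_ci[, "upper"]))
})

test_that("segmented RSS never exceeds the single-line RSS", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- 1:80
    y <- 0.001 * x + rnorm(80, sd = 0.01)
    fit <- fit_segmented(scree_tbl(x, y))
    expect_lte(fit$rss, fit$rss_linear + 1e-15)
  }
})

test_that("degenerate and short series are handled explicitly", {
  flat <- fit_segmented(scree_tbl(1:50, rep(0.3, 50)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$change_point))
  expect_error(fit_segmented(scree_tbl(1:5, 1:5 * 0.1)), "length >= 10")
})

test_that("a pure line with noise rarely yields a significant break", {
  # type-I behaviour of the permutation (Davies-type) existence test
  set.seed(2024)
  n_sig <- 0
  for (r in 1:100) {
    x <- 1:50
    y <- 0.002 * x + rnorm(50, sd = 0.01)
    p <- segmented_permutation_test(scree_tbl(x, y), n_perm = 99)$p_value
    if (p < 0.05) n_sig <- n_sig + 1
  }
  expect_gte(100 - n_sig, 90)
})

test_that("an obvious break is detected by the permutation test", {
  set.seed(5)
  x <- 1:100
  y <- broken_stick_y(x, 0.0002, 0.004, 60, noise_sd = 0.005)
  p <- segmented_permutation_test(scree_tbl(x, y), n_perm = 199)$p_value
  expect_lt(p, 0.05)
})

test_that("slope ratio divides the two segment slopes", {
  fit <- fit_segmented(scree_tbl(1:100, broken_stick_y(1:100, 2e-4, 1e-3, 60)))
  expect_equal(slope_ratio(fit), 5, tolerance = 1e-4)
  # published full-precision slopes give 5.744 (2-digit rounding prints 5.82)
  expect_equal(0.000988 / 0.000172, 5.744, tolerance = 1e-3)
})

test_that("bootstrap interval is reproducible and tight when noiseless", {
  x <- 1:200
  y <- broken_stick_y(x, 2e-4, 1e-3, 120)
  sc <- scree_tbl(x, y)
  ci1 <- bootstrap_changepoint_ci(sc, B = 200, seed = 11)
  ci2 <- bootstrap_changepoint_ci(sc, B = 200, seed = 11)
  expect_equal(as.numeric(ci1), as.numeric(ci2))
  expect_lte(diff(as.numeric(ci1)), 2)
  expect_lte(abs(mean(as.numeric(ci1)) - 120), 1.5)
  expect_error(bootstrap_changepoint_ci(sc, B = 50), "at least 200")
})

test_that("bootstrap interval covers the true change-point", {
  # scaled replication study: noisy series with a known break
  set.seed(77)
  covered <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    x <- 1:200
    y <- broken_stick_y(x, 2e-4, 1.2e-3, 140, noise_sd = 0.006)
    ci <- bootstrap_changepoint_ci(scree_tbl(x, y), B = 200, seed = r)
    if (ci[1] <= 140 && 140 <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.9)
})

test_that("tidy and glance expose the fit in broom shape", {
  x <- 1:100
  fit <- fit_segmented(scree_tbl(x, broken_stick_y(x, 2e-4, 1e-3, 60,
                                                   noise_sd = 0.001)))
  td <- tidy(fit)
  expect_equal(td$term, c("slope1", "slope2"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 100)
  expect_equal(gl$slope_ratio, fit$slope2 / fit$slope1)
})
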