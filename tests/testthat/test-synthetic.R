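test_that("moment matching is analytically exact for the lognormal family", {
  p <- moment_match("lognormal", 40.7, 50.0)
  m <- exp(p$meanlog + p$sdlog^2 / 2)
  s2 <- (exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2)
  expect_equal(m, 40.7, tolerance = 1e-12)
  expect_equal(sqrt(s2), 50.0, tolerance = 1e-12)

  # degenerate limit: sd -> 0 gives sigma -> 0, mu -> log(mean) -> 0 at mean 1
  p0 <- moment_match("lognormal", 1, 1e-9)
  expect_lt(p0$sdlog, 1e-8)
  expect_lt(abs(p0$meanlog), 1e-12)

  expect_error(moment_match("lognormal", -1, 1), "positive")
})

test_that("lognormal sampling hits the published CRP moments", {
  set.seed(101)
  p <- moment_match("lognormal", 40.7, 50.0)
  x <- rlnorm(1e6, p$meanlog, p$sdlog)
  expect_equal(mean(x), 40.7, tolerance = 0.01)   # within 1% (stochastic)
  expect_equal(sd(x), 50.0, tolerance = 0.01)
})

test_that("truncated normal sampling stays near the published Hb mean", {
  spec <- cohort_spec(
    tibble::tibble(name = c("Hb", "x", "y"), family = "normal-truncated",
                   target_mean = c(13.4, 10, 10), target_sd = c(1.82, 2, 2),
                   lower = c(7.8, 0, 0), upper = c(17.9, 20, 20)),
    n_patients = 5000)
  co <- generate_cohort(spec, seed = 5)
  expect_equal(mean(co$Hb), 13.4, tolerance = 0.02)  # truncation bias tolerated
})

test_that("generation is deterministic and respects the contract", {
  spec <- default_cohort_spec()
  a <- generate_cohort(spec, seed = 9)
  b <- generate_cohort(spec, seed = 9)
  expect_identical(mstriad:::cohort_values(a), mstriad:::cohort_values(b))
  expect_identical(a$time, b$time)

  expect_equal(dim(mstriad:::cohort_values(a)), c(366, 20))
  expect_equal(sum(a$event), 76)
  expect_true(all(a$time[a$event == 0] == 365))
  expect_true(all(a$time >= 0 & a$time <= 365))

  # generated values respect every variable's bounds
  ref <- ape_panel_reference()
  vals <- mstriad:::cohort_values(a)
  for (k in seq_len(nrow(ref))) {
    expect_true(all(vals[, ref$name[k]] >= ref$min[k] &
                      vals[, ref$name[k]] <= ref$max[k]))
  }
})

test_that("skewed variables must use the lognormal family", {
  bad <- tibble::tibble(name = c("a", "b", "c"), family = "normal-truncated",
                        target_mean = c(10, 10, 10), target_sd = c(2, 2, 9),
                        lower = 0, upper = 100)
  expect_error(cohort_spec(bad), "lognormal")
})

test_that("invalid correlation matrices are rejected", {
  vars <- tibble::tibble(name = c("a", "b", "c"), family = "lognormal",
                         target_mean = 10, target_sd = 10,
                         lower = 0, upper = 1000)
  notsym <- matrix(c(1, 0.5, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  expect_error(cohort_spec(vars, correlation = notsym), "symmetric")
  notpd <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  spec <- cohort_spec(vars, n_patients = 50, correlation = notpd)
  expect_error(generate_cohort(spec, seed = 1), "positive definite")
})

test_that("copula correlation induces dependence while keeping margins", {
  vars <- tibble::tibble(name = c("a", "b", "c"), family = "lognormal",
                         target_mean = 10, target_sd = 10,
                         lower = 0, upper = 1e6)
  rho <- matrix(0.8, 3, 3); diag(rho) <- 1
  co <- generate_cohort(cohort_spec(vars, n_patients = 2000,
                                    correlation = rho), seed = 2)
  expect_gt(cor(co$a, co$b, method = "spearman"), 0.6)
  expect_equal(mean(co$a), 10, tolerance = 0.1)
})

test_that("zero coupling leaves event-subgroup dispersion unchanged", {
  # null calibration: with disease_coupling = 0 everywhere, a rank-based
  # dispersion test between event and non-event subgroups should reject
  # at alpha = 0.01 in at most a handful of 100 seeds
  spec <- default_cohort_spec()
  p_vals <- vapply(1:100, function(s) {
    co <- generate_cohort(spec, seed = 1000 + s)
    stats::fligner.test(co$CRP, factor(co$event))$p.value
  }, numeric(1))
  expect_gte(sum(p_vals >= 0.01), 95)
})

test_that("positive coupling inflates the event subgroup's spread", {
  # wide bounds so truncation does not mask the dispersion inflation
  vars <- tibble::tibble(name = c("crp", "x", "y"), family = "lognormal",
                         target_mean = 40, target_sd = c(50, 20, 20),
                         lower = 0, upper = 1e5,
                         disease_coupling = c(2, 0, 0))
  co <- generate_cohort(cohort_spec(vars, n_patients = 2000,
                                    event_fraction = 0.25), seed = 17)
  expect_gt(sd(co$crp[co$event == 1]) / sd(co$crp[co$event == 0]), 1.5)
  expect_lt(sd(co$x[co$event == 1]) / sd(co$x[co$event == 0]), 1.3)
})
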