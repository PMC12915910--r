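# Programmatic fixtures shared across test files.

# Random non-negative cohort with lognormal-ish columns.
toy_cohort <- function(n = 10, p = 5, seed = 42, ...) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * p)), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  as_cohort(as.data.frame(m), ...)
}

scree_tbl <- function(x, y) data.frame(rank = x, mean_distance = y)

# Noiseless broken stick: slope b1 up to psi, slope b2 after, continuous.
broken_stick_y <- function(x, b1, b2, psi, intercept = 0, noise_sd = 0) {
  y <- intercept + b1 * x + (b2 - b1) * pmax(0, x - psi)
  if (noise_sd > 0) y <- y + rnorm(length(x), sd = noise_sd)
  y
}
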