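# Independent brute-force oracles and small fixture builders.

# Naive per-test loop classification, written independently of the kernel:
# publication on any uncorrected rejection, true positive when some single
# test has both a relevant effect and a Sidak-level rejection.
oracle_classify <- function(t_values, effect_sizes, alpha, dmin, df,
                            two_sided = TRUE) {
  k <- length(t_values)
  p_crit <- if (two_sided) 1 - alpha / 2 else 1 - alpha
  a_s <- 1 - (1 - alpha)^(1 / k)
  p_crit_s <- if (two_sided) 1 - a_s / 2 else 1 - a_s
  published <- FALSE
  true_positive <- FALSE
  for (j in seq_len(k)) {
    tj <- if (two_sided) abs(t_values[j]) else t_values[j]
    if (tj > qt(p_crit, df)) published <- TRUE
    if (effect_sizes[j] >= dmin && tj > qt(p_crit_s, df)) {
      true_positive <- TRUE
    }
  }
  list(published = published, true_positive = true_positive)
}

# Draws one random classification instance (returns inputs, not results).
random_instance <- function() {
  k <- sample(1:10, 1)
  list(
    t = rnorm(k, mean = sample(c(0, 2), 1), sd = 2),
    d = rexp(k, rate = 1 / 0.25),
    alpha = sample(c(0.05, 0.005, 0.2), 1),
    dmin = 0.2,
    df = runif(1, 3, 120),
    two_sided = sample(c(TRUE, FALSE), 1)
  )
}

# Small, fast parameter set for engine-level tests.
tiny_params <- function(...) {
  phack_params(N = 50L, n_steps = 100L, n_replicates = 2L, ...)
}

# Mean of a normal clipped (not truncated) to [lo, hi]:
# E[min(hi, max(lo, X))], X ~ N(mu, sd).
clipped_normal_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  lo * pnorm(a) + hi * (1 - pnorm(b)) +
    mu * (pnorm(b) - pnorm(a)) + sd * (dnorm(a) - dnorm(b))
}
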