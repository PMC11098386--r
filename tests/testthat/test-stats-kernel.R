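test_that("experiment probability follows the exponential effort cost", {
  expect_identical(experiment_probability(5, 5, 0.01), 1)
  expect_equal(experiment_probability(105, 5, 0.01), exp(-1))
  expect_identical(experiment_probability(20, 5, 0), 1)
  # strictly decreasing in effort for positive eta
  p <- experiment_probability(c(5, 10, 50, 200), 5, 0.01)
  expect_true(all(diff(p) < 0))
  expect_error(experiment_probability(4, 5, 0.01), "Emin")
  expect_error(experiment_probability(20, 5, -1), "eta")
})

test_that("effect-size scale and null prior are mutual inverses", {
  expect_identical(round(scale_from_prior(0.2, 0.8), 4), 0.1243)
  expect_equal(scale_from_prior(0.2, 1 - exp(-1)), 0.2)
  expect_equal(prior_from_scale(0, 0.1243), 0)
  expect_equal(prior_from_scale(0.2, 0.1243), 0.8, tolerance = 1e-3)
  expect_equal(prior_from_scale(0.2, 0.2 / log(2)), 0.5)
  for (p in c(0.5, 0.8, 0.9)) {
    expect_equal(prior_from_scale(0.2, scale_from_prior(0.2, p)), p,
                 tolerance = 1e-12)
  }
  expect_error(scale_from_prior(0.2, 1), "prior_null")
  expect_error(scale_from_prior(0.2, 0), "prior_null")
  expect_error(prior_from_scale(0.2, 0), "d0")
})

test_that("effect-size draws are exponential with the requested scale", {
  set.seed(11)
  d <- sample_effect_sizes(0.1243, 1e6)
  expect_true(all(d >= 0))
  expect_equal(mean(d), 0.1243, tolerance = 3 * 0.1243 / 1000 / 0.1243)
  # empirical CDF at dmin matches the implied null prior
  expect_equal(mean(d <= 0.2), 0.8, tolerance = 0.002 / 0.8)
  set.seed(42)
  a <- sample_effect_sizes(0.5, 3)
  set.seed(42)
  b <- sample_effect_sizes(0.5, 3)
  expect_identical(a, b)
  expect_error(sample_effect_sizes(0.5, 0), "k")
  expect_error(sample_effect_sizes(-1, 3), "scale")
})

test_that("noncentrality treats effort as per-group sample size", {
  expect_identical(noncentrality(0, 20), 0)
  expect_equal(noncentrality(0.2, 50), 1)
  expect_equal(noncentrality(0.5, 20), 0.5 * sqrt(10))
  expect_error(noncentrality(0.2, 1), "df|exceed")
  expect_error(noncentrality(-0.1, 20), "non-negative")
})

test_that("noncentral t draws match closed-form moments and tails", {
  set.seed(21)
  # type-I calibration under the point null
  t0 <- sample_t_statistics(rep(0, 1e5), df = 38)
  crit <- critical_t(0.05, 38, two_sided = TRUE)
  se <- sqrt(0.05 * 0.95 / 1e5)
  expect_lt(abs(mean(abs(t0) > crit) - 0.05), 3 * se)
  # closed-form mean: lambda * sqrt(df/2) * G((df-1)/2) / G(df/2)
  tv <- sample_t_statistics(rep(1, 1e6), df = 98)
  m <- 1 * sqrt(98 / 2) * exp(lgamma(97 / 2) - lgamma(49))
  expect_equal(mean(tv), m, tolerance = 3 * sd(tv) / sqrt(1e6) / m)
  # upper-tail probabilities against the numerical noncentral-t CDF
  for (tstar in c(0, 1.5, 3)) {
    expect_equal(mean(tv > tstar), 1 - pt(tstar, 98, ncp = 1),
                 tolerance = 0.005)
  }
  expect_error(sample_t_statistics(c(0, 1), df = 0), "df")
  expect_error(sample_t_statistics(c(0, -1), df = 10), "lambdas")
})

test_that("critical values come from the central t quantile", {
  expect_equal(critical_t(0.5, 17, two_sided = FALSE), 0)
  expect_equal(critical_t(0.05, 38, two_sided = TRUE), 2.0244,
               tolerance = 1e-4)
  for (df in c(3, 10, 38, 200)) {
    expect_gt(critical_t(0.005, df), critical_t(0.05, df))
  }
  expect_error(critical_t(0, 10), "alpha")
  expect_error(critical_t(1, 10), "alpha")
  expect_error(critical_t(0.05, -1), "df")
})

test_that("Sidak correction shrinks the per-test threshold", {
  expect_equal(sidak_alpha(0.05, 1), 0.05)
  expect_equal(sidak_alpha(0.05, 10), 0.005116, tolerance = 1e-3)
  expect_equal(sidak_alpha(0.005, 5), 1 - 0.995^0.2)
  a <- sidak_alpha(0.05, 1:20)
  expect_true(all(diff(a) < 0))
  expect_true(all(a[-1] < 0.05))
  expect_error(sidak_alpha(0.05, 0), "k")
})

test_that("Sidak-level testing controls family-wise error of k independent tests", {
  set.seed(31)
  n_fam <- 1e5
  se <- sqrt(0.05 * 0.95 / n_fam)
  for (k in c(2, 5, 10)) {
    a_s <- sidak_alpha(0.05, k)
    crit <- critical_t(a_s, 38, two_sided = TRUE)
    tv <- matrix(abs(rt(n_fam * k, df = 38)), ncol = k)
    fwer <- mean(apply(tv > crit, 1, any) > 0)
    expect_lt(abs(fwer - 0.05), 3 * se)
  }
})

test_that("rejection probability is monotone in effort and effect size", {
  set.seed(41)
  n <- 1e5
  crit <- function(E) critical_t(0.05, 2 * E - 2)
  rej <- function(d, E) {
    mean(abs(sample_t_statistics(rep(noncentrality(d, E), n),
                                 2 * E - 2)) > crit(E))
  }
  tol <- 3 * sqrt(0.5 / n)  # 3 SE of a difference, conservative p(1-p) <= 1/4
  pE <- vapply(c(5, 20, 80), function(E) rej(0.5, E), numeric(1))
  expect_true(all(diff(pE) > -tol))
  pd <- vapply(c(0, 0.3, 0.8), function(d) rej(d, 20), numeric(1))
  expect_true(all(diff(pd) > -tol))
})

test_that("outcome classification applies the publication and truth rules", {
  # single relevant effect with an extreme statistic: published true positive
  out <- classify_outcome(10, 0.5, alpha = 0.05, dmin = 0.2, df = 38)
  expect_true(out$published)
  expect_true(out$true_positive)
  # null effect rejected: published false positive
  out <- classify_outcome(3, 0.1, alpha = 0.05, dmin = 0.2, df = 38)
  expect_true(out$published)
  expect_false(out$true_positive)
  # nothing significant: nothing published
  out <- classify_outcome(c(0.5, -1), c(0.5, 0.1), alpha = 0.05,
                          dmin = 0.2, df = 38)
  expect_false(out$published)
  expect_false(out$true_positive)
  expect_identical(out$n_tests, 2L)
  expect_error(classify_outcome(c(1, 2), 0.5, 0.05, 0.2, 38), "equal length")
})

test_that("classification matches an independent brute-force oracle", {
  set.seed(51)
  for (i in seq_len(2000)) {
    inst <- random_instance()
    got <- classify_outcome(inst$t, inst$d, inst$alpha, inst$dmin, inst$df,
                            inst$two_sided)
    want <- oracle_classify(inst$t, inst$d, inst$alpha, inst$dmin, inst$df,
                            inst$two_sided)
    expect_identical(got$published, want$published)
    expect_identical(got$true_positive, want$true_positive)
    # invariant: a true positive is always published
    expect_true(!got$true_positive || got$published)
  }
})

test_that("bulk classification agrees with the per-experiment path", {
  set.seed(61)
  for (two_sided in c(TRUE, FALSE)) {
    k <- sample(1:8, 40, replace = TRUE)
    df <- runif(40, 4, 100)
    t <- rnorm(sum(k), 1, 2)
    d <- rexp(sum(k), 4)
    bulk <- phacksim:::classify_outcomes_bulk(
      t, d, alpha = 0.05, dmin = 0.2, df = df, k = k, two_sided = two_sided)
    grp <- rep.int(seq_along(k), k)
    for (i in seq_along(k)) {
      one <- classify_outcome(t[grp == i], d[grp == i], 0.05, 0.2, df[i],
                              two_sided)
      expect_identical(bulk$published[i], one$published)
      expect_identical(bulk$true_positive[i], one$true_positive)
    }
  }
})

test_that("analytic literature FPR reproduces the threshold comparison", {
  expect_equal(analytic_fpr(0.05, 1, 0.1), 1 / 3)
  expect_equal(round(100 * analytic_fpr(0.05, 1, 0.1)), 33)
  expect_equal(round(100 * analytic_fpr(0.005, 1, 0.1)), 5)
  expect_lt(analytic_fpr(0.05, 1, 1e9), 1e-9)
  expect_error(analytic_fpr(0.05, 1, 0), "odds")
  expect_error(analytic_fpr(0.05, 0, 0.1), "power")
})
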