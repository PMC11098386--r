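# Closed-form statistics and single-experiment stochastic machinery.
# All simulation draws consume R's global RNG; callers control seeding.

#' Probability of conducting an experiment in one time step
#'
#' Effort slows researchers down: the per-step probability of completing an
#' experiment decays exponentially in the effort applied beyond the minimum,
#' `exp(-eta * (E - Emin))`.  At `E = Emin` an experiment is certain; with
#' `eta = 0` effort carries no time cost.
#'
#' @param E Effort applied (must be at least `Emin`).
#' @param Emin Lower bound on effort.
#' @param eta Non-negative decay parameter; larger values make extra effort
#'   costlier in lost productivity.
#' @return Probability in `(0, 1]`, vectorised over `E`.
#' @examples
#' experiment_probability(20, 5, 0.01)
#' @export
experiment_probability <- function(E, Emin, eta) {
  stopifnot(is.numeric(E), is.numeric(Emin), is.numeric(eta))
  if (any(E < Emin)) {
    stop("effort `E` must be >= `Emin` (", Emin, ")", call. = FALSE)
  }
  if (eta < 0) stop("`eta` must be non-negative", call. = FALSE)
  exp(-eta * (E - Emin))
}

#' Effect-size scale implied by the prior probability of the null
#'
#' True Cohen's d effect sizes are exponentially distributed with scale `d0`;
#' an experiment counts as a true null when its effect is at or below the
#' minimally relevant size `dmin`.  Fixing the prior probability of the null
#' `P[H0] = P(d <= dmin)` therefore determines the scale:
#' `d0 = -dmin / log(1 - P[H0])`.
#'
#' @param dmin Minimally relevant effect size (> 0, Cohen's d units).
#' @param prior_null Prior probability of a true null, in `(0, 1)`.
#' @return The exponential scale parameter `d0`.
#' @examples
#' scale_from_prior(0.2, 0.8)  # 0.1243
#' @seealso [prior_from_scale()] for the inverse.
#' @export
scale_from_prior <- function(dmin, prior_null) {
  if (!is.numeric(dmin) || dmin <= 0) {
    stop("`dmin` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(prior_null) || prior_null <= 0 || prior_null >= 1) {
    stop("`prior_null` must lie strictly between 0 and 1", call. = FALSE)
  }
  -dmin / log(1 - prior_null)
}

#' Prior probability of the null implied by an effect-size scale
#'
#' Inverse of [scale_from_prior()]: with effect sizes exponential at scale
#' `d0`, the probability that an effect is at or below `dmin` is
#' `1 - exp(-dmin / d0)`.
#'
#' @param dmin Minimally relevant effect size (>= 0).
#' @param d0 Exponential scale parameter (> 0).
#' @return Probability in `[0, 1)`.
#' @export
prior_from_scale <- function(dmin, d0) {
  if (!is.numeric(dmin) || dmin < 0) {
    stop("`dmin` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(d0) || d0 <= 0) {
    stop("`d0` must be positive", call. = FALSE)
  }
  1 - exp(-dmin / d0)
}

#' Draw true effect sizes for the hypotheses of one experiment
#'
#' @param scale Exponential scale (mean) of the effect-size distribution.
#' @param k Number of hypotheses (>= 1).
#' @return Numeric vector of `k` non-negative effect sizes.
#' @export
sample_effect_sizes <- function(scale, k) {
  if (!is.numeric(scale) || scale <= 0) {
    stop("`scale` must be positive", call. = FALSE)
  }
  if (!is.numeric(k) || k < 1) stop("`k` must be at least 1", call. = FALSE)
  stats::rexp(as.integer(k), rate = 1 / scale)
}

#' Noncentrality parameter of a two-sample t test
#'
#' With effort `E` read as the per-group sample size of a balanced two-sample
#' design, a true standardised effect `d` gives noncentrality
#' `lambda = d * sqrt(E / 2)`.  Effort evolves continuously, so `E` (and the
#' degrees of freedom `2E - 2`) need not be integers.
#'
#' @param d True effect size (>= 0).
#' @param E Effort / per-group sample size (> 1, so that `2E - 2 > 0`).
#' @return The noncentrality parameter, vectorised over `d` and `E`.
#' @export
noncentrality <- function(d, E) {
  if (any(d < 0)) stop("`d` must be non-negative", call. = FALSE)
  if (any(E <= 1)) {
    stop("`E` must exceed 1 (degrees of freedom 2E - 2 must be positive)",
         call. = FALSE)
  }
  d * sqrt(E / 2)
}

#' Draw t statistics from the noncentral t distribution
#'
#' One independent draw per noncentrality parameter, all sharing `df` degrees
#' of freedom.  With `lambda = 0` the marginal is the central t.
#'
#' @param lambdas Numeric vector of non-negative noncentrality parameters.
#' @param df Degrees of freedom (> 0, may be non-integer).
#' @return Numeric vector of the same length as `lambdas`.
#' @export
sample_t_statistics <- function(lambdas, df) {
  if (!is.numeric(df) || any(df <= 0)) {
    stop("`df` must be positive", call. = FALSE)
  }
  if (any(!is.finite(lambdas)) || any(lambdas < 0)) {
    stop("`lambdas` must be finite and non-negative", call. = FALSE)
  }
  stats::rt(length(lambdas), df = df, ncp = lambdas)
}

#' Critical t value at a significance threshold
#'
#' @param alpha Significance threshold in `(0, 1)`.
#' @param df Degrees of freedom (> 0).
#' @param two_sided Two-sided rejection (`P(|T| > t*) = alpha`) or one-sided
#'   (`P(T > t*) = alpha`).
#' @return The critical value `t*`, vectorised over `df`.
#' @export
critical_t <- function(alpha, df, two_sided = TRUE) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(df) || any(df <= 0)) {
    stop("`df` must be positive", call. = FALSE)
  }
  p <- if (two_sided) 1 - alpha / 2 else 1 - alpha
  stats::qt(p, df)
}

#' Sidak-corrected per-test threshold
#'
#' `alpha_S = 1 - (1 - alpha)^(1/k)` controls the family-wise error of `k`
#' independent tests at `alpha`.  The simulated researchers never apply it;
#' the simulator uses it privately to adjudicate which published findings
#' count as true positives.
#'
#' @param alpha Family-wise threshold in `(0, 1)`.
#' @param k Number of hypotheses (integer >= 1, vectorised).
#' @return Corrected per-test threshold(s); equals `alpha` at `k = 1`.
#' @export
sidak_alpha <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(k < 1)) stop("`k` must be at least 1", call. = FALSE)
  1 - (1 - alpha)^(1 / k)
}

#' Classify one experiment's publication and truth status
#'
#' A researcher publishes when at least one of the `k` test statistics exceeds
#' the uncorrected critical value at `alpha` (no multiplicity correction is
#' applied by the agent).  The simulator scores the result a true positive only
#' if some single test simultaneously (1) had a true effect of at least `dmin`
#' and (2) exceeded the Sidak-corrected critical value for `k` tests.  A
#' published result that is not a true positive is a false positive.
#'
#' @param t_values Numeric vector of `k` simulated t statistics.
#' @param effect_sizes Numeric vector of the `k` true effect sizes behind them.
#' @param alpha Significance threshold used by the researcher.
#' @param dmin Minimally relevant effect size.
#' @param df Degrees of freedom of the tests.
#' @param two_sided Rejection sidedness (default two-sided).
#' @return An object of class `experiment_outcome`: a list with `published`,
#'   `true_positive`, `n_tests`, `effect_sizes` and `t_values`.
#' @examples
#' classify_outcome(t_values = 5, effect_sizes = 0.5,
#'                  alpha = 0.05, dmin = 0.2, df = 38)
#' @export
classify_outcome <- function(t_values, effect_sizes, alpha, dmin, df,
                             two_sided = TRUE) {
  k <- length(t_values)
  if (k < 1L || length(effect_sizes) != k) {
    stop("`t_values` and `effect_sizes` must have equal length k >= 1",
         call. = FALSE)
  }
  tv <- if (two_sided) abs(t_values) else t_values
  t_crit <- critical_t(alpha, df, two_sided)
  t_crit_sidak <- critical_t(sidak_alpha(alpha, k), df, two_sided)
  published <- any(tv > t_crit)
  true_positive <- any(effect_sizes >= dmin & tv > t_crit_sidak)
  structure(
    list(published = published, true_positive = true_positive,
         n_tests = k, effect_sizes = effect_sizes, t_values = t_values),
    class = "experiment_outcome"
  )
}

#' @export
print.experiment_outcome <- function(x, ...) {
  cat("<experiment_outcome> k =", x$n_tests,
      "| published:", x$published,
      "| true positive:", x$true_positive, "\n")
  invisible(x)
}

# Vectorised classification for a batch of experiments, used by the engine.
# Tests are laid out contiguously per experiment: `k` gives the number of
# tests of each experiment, and `t_values`/`effect_sizes` stack the per-test
# draws in the same experiment order (lengths sum(k)).  `df` is per experiment.
# Returns logical vectors `published` / `true_positive`, one per experiment.
classify_outcomes_bulk <- function(t_values, effect_sizes, alpha, dmin, df, k,
                                   two_sided = TRUE) {
  n <- length(k)
  stopifnot(length(df) == n,
            length(t_values) == sum(k),
            length(effect_sizes) == sum(k))
  grp <- rep.int(seq_len(n), k)
  tv <- if (two_sided) abs(t_values) else t_values
  t_crit <- critical_t(alpha, df, two_sided)
  t_crit_sidak <- critical_t(sidak_alpha(alpha, k), df, two_sided)
  rej <- tv > t_crit[grp]
  tp_test <- (effect_sizes >= dmin) & (tv > t_crit_sidak[grp])
  published <- rowsum(as.integer(rej), grp, reorder = FALSE)[, 1L] > 0L
  true_positive <- rowsum(as.integer(tp_test), grp, reorder = FALSE)[, 1L] > 0L
  list(published = unname(published), true_positive = unname(true_positive))
}

#' Analytic false-positive rate of the published literature
#'
#' Among nominally significant results, the expected fraction that are false
#' positives is `alpha / (alpha + power * prior_odds_alt)`, where
#' `prior_odds_alt` is the prior odds of the alternative against the null.
#' With prior odds 1:10 and power 1, a threshold of 0.05 yields a 33%
#' false-positive rate, which falls to about 5% at 0.005.
#'
#' @param alpha Significance threshold in `(0, 1)`, vectorised.
#' @param power Statistical power in `(0, 1]`.
#' @param prior_odds_alt Prior odds of the alternative (> 0), e.g. `0.1` for
#'   odds of 1:10.
#' @return Expected false-positive fraction of significant results.
#' @examples
#' analytic_fpr(c(0.05, 0.005), power = 1, prior_odds_alt = 0.1)
#' @export
analytic_fpr <- function(alpha, power, prior_odds_alt) {
  if (any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(power <= 0) || any(power > 1)) {
    stop("`power` must lie in (0, 1]", call. = FALSE)
  }
  if (any(prior_odds_alt <= 0)) {
    stop("`prior_odds_alt` must be positive", call. = FALSE)
  }
  alpha / (alpha + power * prior_odds_alt)
}
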