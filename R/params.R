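# Model parameters and scenario definitions.

.param_defaults <- list(
  N = 2000L,          # number of researchers
  e0 = 20,            # initial effort, applied by all researchers
  k0 = 1L,            # initial number of hypotheses per experiment
  emin = 5,           # minimum effort
  kmin = 1L,          # minimum number of hypotheses
  emax = 500,         # maximum effort
  kmax = 50L,         # maximum number of hypotheses
  sigma_E = 10,       # sd of effort mutation at replacement
  sigma_k = 2,        # sd of hypothesis-count mutation at replacement
  prior_null = 0.8,   # prior probability of a true null, P(d <= dmin)
  dmin = 0.2,         # minimally relevant effect size (Cohen's d)
  eta = 0.01,         # effort cost on the experiment rate
  p_retire = 0.002,   # per-step retirement probability
  LM = 0.1,           # fraction of top researchers eligible as parents
  n_steps = 50000L,
  n_replicates = 100L,
  base_seed = 1L,
  two_sided = TRUE,
  hierarchical_effects = TRUE
)

#' Model parameters
#'
#' Builds a validated parameter set for the simulation.  Defaults are the
#' model's standard configuration: 2000 researchers starting at effort 20 and
#' one hypothesis per experiment, effort bounded in \[5, 500\] and hypothesis
#' counts in \[1, 50\], mutation standard deviations 10 (effort) and 2
#' (hypotheses), null prior 0.8, minimally relevant effect size 0.2, effort
#' cost 0.01, retirement probability 0.002 per step, and a parent pool of the
#' top 10% of researchers by publication count.
#'
#' The exponential effect-size scale `d0` is derived from `dmin` and
#' `prior_null` via [scale_from_prior()] and stored alongside.
#'
#' @param ... Named overrides of any default (see Details in
#'   `vignette("phacking-threshold-model")`).  Unknown names are an error.
#' @return An object of class `phack_params` (a named list).
#' @examples
#' p <- phack_params(N = 200, n_steps = 5000)
#' p$d0
#' @export
phack_params <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  params <- .param_defaults
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, c(names(params), "d0"))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    params[nm] <- overrides
  }
  for (f in c("N", "k0", "kmin", "kmax", "n_steps", "n_replicates",
              "base_seed")) {
    params[[f]] <- as.integer(params[[f]])
  }
  params$d0 <- scale_from_prior(params$dmin, params$prior_null)
  params <- structure(params, class = "phack_params")
  validate_params(params)
  params
}

#' @rdname phack_params
#' @param params A `phack_params` object.
#' @export
validate_params <- function(params) {
  with(params, {
    if (N < 1L) stop("`N` must be at least 1", call. = FALSE)
    if (emin <= 1) stop("`emin` must exceed 1 (df = 2E - 2 > 0)", call. = FALSE)
    if (emin > emax) stop("`emin` must not exceed `emax`", call. = FALSE)
    if (kmin < 1L) stop("`kmin` must be at least 1", call. = FALSE)
    if (kmin > kmax) stop("`kmin` must not exceed `kmax`", call. = FALSE)
    if (e0 < emin || e0 > emax) {
      stop("`e0` must lie in [emin, emax]", call. = FALSE)
    }
    if (k0 < kmin || k0 > kmax) {
      stop("`k0` must lie in [kmin, kmax]", call. = FALSE)
    }
    if (sigma_E < 0 || sigma_k < 0) {
      stop("mutation standard deviations must be non-negative", call. = FALSE)
    }
    if (prior_null <= 0 || prior_null >= 1) {
      stop("`prior_null` must lie strictly between 0 and 1", call. = FALSE)
    }
    if (dmin <= 0) stop("`dmin` must be positive", call. = FALSE)
    if (eta < 0) stop("`eta` must be non-negative", call. = FALSE)
    if (p_retire < 0 || p_retire > 1) {
      stop("`p_retire` must lie in [0, 1]", call. = FALSE)
    }
    if (LM <= 0 || LM > 1) stop("`LM` must lie in (0, 1]", call. = FALSE)
    if (n_steps < 0L) stop("`n_steps` must be non-negative", call. = FALSE)
    if (n_replicates < 1L) {
      stop("`n_replicates` must be at least 1", call. = FALSE)
    }
  })
  invisible(params)
}

#' @export
print.phack_params <- function(x, ...) {
  cat("<phack_params>\n")
  cat(sprintf("  population N = %d, %d steps x %d replicates\n",
              x$N, x$n_steps, x$n_replicates))
  cat(sprintf("  effort: e0 = %g in [%g, %g], sigma_E = %g, eta = %g\n",
              x$e0, x$emin, x$emax, x$sigma_E, x$eta))
  cat(sprintf("  hypotheses: k0 = %d in [%d, %d], sigma_k = %g\n",
              x$k0, x$kmin, x$kmax, x$sigma_k))
  cat(sprintf("  effects: prior_null = %g, dmin = %g, d0 = %.4f (%s)\n",
              x$prior_null, x$dmin, x$d0,
              if (x$hierarchical_effects) "hierarchical" else "flat"))
  cat(sprintf("  turnover: p_retire = %g, parent pool LM = %g\n",
              x$p_retire, x$LM))
  invisible(x)
}

#' Reduced- and full-scale presets
#'
#' `full` is the standard configuration (N = 2000, 50000 steps, 100
#' replicates); `reduced` is a desk-scale preset (N = 200, 5000 steps, 20
#' replicates) that preserves the qualitative dynamics at a small fraction of
#' the cost.
#'
#' @param preset `"full"` or `"reduced"`.
#' @param ... Further overrides passed to [phack_params()].
#' @return A `phack_params` object.
#' @export
preset_params <- function(preset = c("reduced", "full"), ...) {
  preset <- match.arg(preset)
  base <- if (preset == "full") {
    list()
  } else {
    list(N = 200L, n_steps = 5000L, n_replicates = 20L)
  }
  overrides <- list(...)
  base[names(overrides)] <- overrides
  do.call(phack_params, base)
}

#' Simulation scenarios
#'
#' Three regimes are compared: `single` (every researcher tests exactly one
#' hypothesis, threshold 0.05), `multi_05` (multiple hypotheses allowed,
#' threshold 0.05) and `multi_005` (multiple hypotheses allowed, threshold
#' 0.005).
#'
#' @param name One of `"single"`, `"multi_05"`, `"multi_005"`.
#' @return An object of class `phack_scenario` with fields `name`, `alpha`
#'   and `multi_allowed`.
#' @examples
#' phack_scenario("multi_005")
#' @export
phack_scenario <- function(name = c("single", "multi_05", "multi_005")) {
  name <- match.arg(name)
  alpha <- switch(name, single = 0.05, multi_05 = 0.05, multi_005 = 0.005)
  structure(
    list(name = name, alpha = alpha, multi_allowed = name != "single"),
    class = "phack_scenario"
  )
}

#' @export
print.phack_scenario <- function(x, ...) {
  cat(sprintf("<phack_scenario> %s: alpha = %g, %s\n", x$name, x$alpha,
              if (x$multi_allowed) "multiple hypotheses allowed"
              else "single hypothesis"))
  invisible(x)
}

as_scenario <- function(x) {
  if (inherits(x, "phack_scenario")) x else phack_scenario(x)
}
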