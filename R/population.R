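# Agent state, initialisation, retirement, and evolutionary replacement.
# A population is a list of parallel vectors (one element per living agent):
# effort, k, value, age, d_scale, n_true_pos, n_false_pos.

new_population <- function(effort, k, value, age, d_scale,
                           n_true_pos, n_false_pos) {
  structure(
    list(effort = effort, k = as.integer(k), value = as.integer(value),
         age = as.integer(age), d_scale = d_scale,
         n_true_pos = as.integer(n_true_pos),
         n_false_pos = as.integer(n_false_pos)),
    class = "phack_population"
  )
}

draw_d_scale <- function(n, params) {
  if (params$hierarchical_effects) {
    stats::rexp(n, rate = 1 / params$d0)
  } else {
    rep(params$d0, n)
  }
}

#' Initialise a researcher population
#'
#' All researchers start with effort `e0`, hypothesis count `k0` (forced to 1
#' in the single-hypothesis scenario), zero publications and age zero.  Each
#' receives a personal effect-size scale `d_i`: a fresh exponential draw at
#' scale `d0` in the hierarchical mode (default), or `d0` itself in the flat
#' mode.
#'
#' @param params A [phack_params()] object.
#' @param scenario A [phack_scenario()] (or its name).
#' @return An object of class `phack_population`.
#' @export
init_population <- function(params, scenario) {
  scenario <- as_scenario(scenario)
  validate_params(params)
  N <- params$N
  k0 <- if (scenario$multi_allowed) params$k0 else 1L
  new_population(
    effort = rep(params$e0, N),
    k = rep(k0, N),
    value = integer(N),
    age = integer(N),
    d_scale = draw_d_scale(N, params),
    n_true_pos = integer(N),
    n_false_pos = integer(N)
  )
}

population_size <- function(pop) length(pop$effort)

#' @export
print.phack_population <- function(x, ...) {
  cat(sprintf(
    "<phack_population> %d researchers | median effort %.1f | median k %d | %d publications (%d FP)\n",
    population_size(x), stats::median(x$effort),
    as.integer(stats::median(x$k)), sum(x$value), sum(x$n_false_pos)))
  invisible(x)
}

validate_population <- function(pop, params = NULL) {
  n <- population_size(pop)
  lens <- vapply(pop, length, integer(1))
  if (any(lens != n)) stop("population vectors have unequal length")
  if (any(pop$value != pop$n_true_pos + pop$n_false_pos)) {
    stop("value must equal n_true_pos + n_false_pos")
  }
  if (!is.null(params)) {
    if (any(pop$effort < params$emin | pop$effort > params$emax)) {
      stop("effort outside [emin, emax]")
    }
    if (any(pop$k < params$kmin | pop$k > params$kmax)) {
      stop("k outside [kmin, kmax]")
    }
  }
  invisible(pop)
}

#' Retirement draws for one time step
#'
#' Each researcher independently retires with probability `p_retire`,
#' producing an exponentially distributed career length.
#'
#' @param pop A `phack_population`.
#' @param p_retire Per-step retirement probability in `[0, 1]`.
#' @return Integer indices of retiring researchers (possibly empty).
#' @export
retire <- function(pop, p_retire) {
  if (p_retire < 0 || p_retire > 1) {
    stop("`p_retire` must lie in [0, 1]", call. = FALSE)
  }
  which(stats::runif(population_size(pop)) < p_retire)
}

#' Spawn replacement researchers
#'
#' New entrants copy their methods (effort, hypothesis count) from a parent
#' drawn uniformly from the top `ceiling(LM * N)` survivors ranked by value
#' (ties broken at random), then mutate: effort gets a `Normal(0, sigma_E)`
#' perturbation clipped to `[emin, emax]`; the hypothesis count gets a
#' `Normal(0, sigma_k)` perturbation rounded to the nearest integer and
#' clipped to `[kmin, kmax]` (held at 1 in the single-hypothesis scenario).
#' Entrants start with zero publications, age zero, and a fresh personal
#' effect-size scale.
#'
#' @param pop Survivor population (after retirements).
#' @param n_new Number of researchers to create (>= 0).
#' @param params A [phack_params()] object.
#' @param scenario A [phack_scenario()] (or its name).
#' @return A `phack_population` of the `n_new` entrants.
#' @export
spawn_replacements <- function(pop, n_new, params, scenario) {
  scenario <- as_scenario(scenario)
  n_surv <- population_size(pop)
  if (n_surv < 1L) stop("no surviving researchers to select parents from",
                        call. = FALSE)
  if (n_new < 0L) stop("`n_new` must be non-negative", call. = FALSE)
  if (n_new == 0L) {
    return(new_population(numeric(0), integer(0), integer(0), integer(0),
                          numeric(0), integer(0), integer(0)))
  }
  n_top <- min(ceiling(params$LM * params$N), n_surv)
  ord <- order(-pop$value, stats::runif(n_surv))
  pool <- ord[seq_len(n_top)]
  parents <- pool[sample.int(n_top, n_new, replace = TRUE)]
  effort <- pmin(pmax(pop$effort[parents] +
                        stats::rnorm(n_new, 0, params$sigma_E),
                      params$emin), params$emax)
  k <- if (scenario$multi_allowed) {
    pmin(pmax(pop$k[parents] +
                as.integer(round(stats::rnorm(n_new, 0, params$sigma_k))),
              params$kmin), params$kmax)
  } else {
    rep(1L, n_new)
  }
  new_population(
    effort = effort, k = k, value = integer(n_new), age = integer(n_new),
    d_scale = draw_d_scale(n_new, params),
    n_true_pos = integer(n_new), n_false_pos = integer(n_new)
  )
}

bind_populations <- function(a, b) {
  new_population(
    effort = c(a$effort, b$effort), k = c(a$k, b$k),
    value = c(a$value, b$value), age = c(a$age, b$age),
    d_scale = c(a$d_scale, b$d_scale),
    n_true_pos = c(a$n_true_pos, b$n_true_pos),
    n_false_pos = c(a$n_false_pos, b$n_false_pos)
  )
}

subset_population <- function(pop, keep) {
  new_population(
    effort = pop$effort[keep], k = pop$k[keep], value = pop$value[keep],
    age = pop$age[keep], d_scale = pop$d_scale[keep],
    n_true_pos = pop$n_true_pos[keep], n_false_pos = pop$n_false_pos[keep]
  )
}
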