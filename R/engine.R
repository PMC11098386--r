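# Discrete-time simulation loop: experiments, publication, truth bookkeeping,
# then retirement/replacement, for full replicated scenario runs.

#' Summarise a population
#'
#' Per-step summary statistics: medians across living researchers of effort,
#' hypothesis count, value, and career false-positive fraction (each agent's
#' FP / (TP + FP), agents with no publications excluded; `NA` if nobody has
#' published), plus the pooled running false-positive rate
#' (total FP / total publications of living researchers).
#'
#' All entries are symmetric in the agents, so the summary is invariant to
#' agent ordering.
#'
#' @param pop A `phack_population`.
#' @return Named numeric vector with elements `median_effort`, `median_k`,
#'   `median_value`, `median_fp_frac`, `pooled_fp_rate`.
#' @export
summarize_population <- function(pop) {
  pubs <- pop$value > 0L
  fp_frac <- if (any(pubs)) {
    stats::median(pop$n_false_pos[pubs] / pop$value[pubs])
  } else {
    NA_real_
  }
  total_pubs <- sum(pop$value)
  pooled <- if (total_pubs > 0L) sum(pop$n_false_pos) / total_pubs else NA_real_
  c(median_effort = stats::median(pop$effort),
    median_k = stats::median(as.numeric(pop$k)),
    median_value = stats::median(as.numeric(pop$value)),
    median_fp_frac = fp_frac,
    pooled_fp_rate = pooled)
}

#' Advance the simulation by one time step
#'
#' All researchers act synchronously against the beginning-of-step state:
#' each conducts an experiment with probability
#' [experiment_probability()]`(E, emin, eta)`; a conducted experiment draws
#' `k` true effect sizes from the agent's personal exponential scale,
#' simulates `k` noncentral-t statistics with `df = 2E - 2` and
#' `lambda = d * sqrt(E/2)`, and is classified with the scenario's threshold
#' (publication on any uncorrected rejection; truth via the Sidak-corrected
#' threshold).  Any publication increments the agent's value and the
#' corresponding true/false-positive tally.  Retirement and replacement then
#' restore the population to size `N`, and survivors age by one step.
#'
#' @param pop A `phack_population`.
#' @param scenario A [phack_scenario()] (or its name).
#' @param params A [phack_params()] object.
#' @return List with elements `population` (updated) and `summary`
#'   (the end-of-step [summarize_population()] vector).
#' @export
sim_step <- function(pop, scenario, params) {
  scenario <- as_scenario(scenario)
  N <- population_size(pop)

  conduct <- stats::runif(N) <
    experiment_probability(pop$effort, params$emin, params$eta)
  idx <- which(conduct)
  if (length(idx)) {
    ki <- pop$k[idx]
    grp <- rep.int(seq_along(idx), ki)
    d <- stats::rexp(sum(ki), rate = rep.int(1 / pop$d_scale[idx], ki))
    E_test <- pop$effort[idx][grp]
    tv <- sample_t_statistics(noncentrality(d, E_test), df = 2 * E_test - 2)
    cls <- classify_outcomes_bulk(
      tv, d, alpha = scenario$alpha, dmin = params$dmin,
      df = 2 * pop$effort[idx] - 2, k = ki, two_sided = params$two_sided)
    pub <- idx[cls$published]
    tp <- idx[cls$published & cls$true_positive]
    fp <- idx[cls$published & !cls$true_positive]
    pop$value[pub] <- pop$value[pub] + 1L
    pop$n_true_pos[tp] <- pop$n_true_pos[tp] + 1L
    pop$n_false_pos[fp] <- pop$n_false_pos[fp] + 1L
  }

  retiring <- retire(pop, params$p_retire)
  if (length(retiring)) {
    pop <- subset_population(pop, -retiring)
    pop$age <- pop$age + 1L
    newcomers <- spawn_replacements(pop, N - population_size(pop),
                                    params, scenario)
    pop <- bind_populations(pop, newcomers)
  } else {
    pop$age <- pop$age + 1L
  }

  list(population = pop, summary = summarize_population(pop))
}

#' Run one seeded replicate
#'
#' Seeds the RNG, initialises the population and advances `n_steps` steps,
#' recording the per-step summary and the final population.  Identical
#' parameters and seed give bit-identical results.
#'
#' @param params A [phack_params()] object (`n_steps` controls run length).
#' @param scenario A [phack_scenario()] (or its name).
#' @param seed Integer seed for this replicate.
#' @return An object of class `phack_run`: list with `summary` (data.frame,
#'   one row per step), `final_population`, `fp_rate` (pooled cumulative
#'   false-positive rate of the final living researchers, see
#'   [cumulative_fp_rate()]), `n_false_pos` / `n_publications` totals over the
#'   final population, and the `scenario`, `prior_null` and `seed` used.
#' @export
run_replicate <- function(params, scenario, seed) {
  scenario <- as_scenario(scenario)
  validate_params(params)
  set.seed(as.integer(seed))
  pop <- init_population(params, scenario)
  n_steps <- params$n_steps
  rec <- matrix(NA_real_, nrow = n_steps, ncol = 5L,
                dimnames = list(NULL, c("median_effort", "median_k",
                                        "median_value", "median_fp_frac",
                                        "pooled_fp_rate")))
  for (s in seq_len(n_steps)) {
    out <- sim_step(pop, scenario, params)
    pop <- out$population
    rec[s, ] <- out$summary
  }
  summary_df <- data.frame(step = seq_len(n_steps), rec)
  structure(
    list(summary = summary_df,
         final_population = pop,
         fp_rate = suppressWarnings(cumulative_fp_rate(pop)),
         n_false_pos = sum(pop$n_false_pos),
         n_publications = sum(pop$value),
         scenario = scenario$name,
         alpha = scenario$alpha,
         prior_null = params$prior_null,
         seed = as.integer(seed)),
    class = "phack_run"
  )
}

#' @export
print.phack_run <- function(x, ...) {
  cat(sprintf(
    "<phack_run> %s (alpha = %g), prior_null = %g, seed %d, %d steps\n",
    x$scenario, x$alpha, x$prior_null, x$seed, nrow(x$summary)))
  cat(sprintf("  final cumulative FP rate %.3f (%d FP / %d publications)\n",
              x$fp_rate, x$n_false_pos, x$n_publications))
  invisible(x)
}

#' Deterministic per-cell replicate seeds
#'
#' Derives a distinct, reproducible seed for every (scenario, prior,
#' replicate) cell of a grid from one base seed, so any cell can be re-run in
#' isolation.  Supports up to 4 scenarios, 4 priors and 256 replicates; the
#' result always fits a 32-bit integer.
#'
#' @param base_seed Integer master seed.
#' @param scenario_idx,prior_idx,replicate 1-based cell coordinates.
#' @return Integer seed.
#' @export
replicate_seed <- function(base_seed, scenario_idx, prior_idx, replicate) {
  stopifnot(scenario_idx >= 1, scenario_idx <= 4,
            prior_idx >= 1, prior_idx <= 4,
            replicate >= 1, replicate <= 256)
  as.integer((as.numeric(base_seed) %% 524287) * 4096 +
               (scenario_idx - 1) * 1024 + (prior_idx - 1) * 256 +
               (replicate - 1))
}

#' Run the full scenario-by-prior experiment grid
#'
#' Independent seeded replicates for every (scenario, prior) combination.
#' Per-cell seeds derive deterministically from `base_seed` via
#' [replicate_seed()].
#'
#' @param params A [phack_params()] object; `prior_null` is overridden per
#'   grid cell and `n_replicates` controls replicates unless `n_replicates`
#'   is supplied here.
#' @param scenarios Character vector of scenario names (or list of
#'   [phack_scenario()] objects).
#' @param priors Numeric vector of null priors to sweep.
#' @param n_replicates Number of replicates per cell (default from `params`).
#' @param base_seed Master seed (default from `params`).
#' @param progress Print a line per completed cell.
#' @return An object of class `phack_grid`: list with `runs` (list of
#'   `phack_run`, named `<scenario>|<prior>|<replicate>`) and `index`
#'   (data.frame with one row per run: scenario, alpha, prior_null,
#'   replicate, seed, fp_rate, n_false_pos, n_publications).
#' @export
run_experiment_grid <- function(params,
                                scenarios = c("single", "multi_05",
                                              "multi_005"),
                                priors = params$prior_null,
                                n_replicates = params$n_replicates,
                                base_seed = params$base_seed,
                                progress = FALSE) {
  if (!length(scenarios) || !length(priors)) {
    stop("`scenarios` and `priors` must be non-empty", call. = FALSE)
  }
  scenarios <- lapply(scenarios, as_scenario)
  runs <- list()
  rows <- list()
  for (si in seq_along(scenarios)) {
    for (pi in seq_along(priors)) {
      cell_params <- phack_params(utils::modifyList(
        unclass(params)[setdiff(names(unclass(params)), "d0")],
        list(prior_null = priors[[pi]], n_replicates = as.integer(n_replicates))
      ))
      for (r in seq_len(n_replicates)) {
        seed <- replicate_seed(base_seed, si, pi, r)
        run <- run_replicate(cell_params, scenarios[[si]], seed)
        key <- sprintf("%s|%g|%d", scenarios[[si]]$name, priors[[pi]], r)
        runs[[key]] <- run
        rows[[key]] <- data.frame(
          scenario = scenarios[[si]]$name, alpha = scenarios[[si]]$alpha,
          prior_null = priors[[pi]], replicate = r, seed = seed,
          fp_rate = run$fp_rate, n_false_pos = run$n_false_pos,
          n_publications = run$n_publications)
      }
      if (progress) {
        message(sprintf("completed %s @ prior %g (%d replicates)",
                        scenarios[[si]]$name, priors[[pi]], n_replicates))
      }
    }
  }
  structure(
    list(runs = runs, index = do.call(rbind, c(rows, make.row.names = FALSE))),
    class = "phack_grid"
  )
}

#' @export
print.phack_grid <- function(x, ...) {
  cat(sprintf("<phack_grid> %d runs across %d scenario x prior cells\n",
              nrow(x$index),
              nrow(unique(x$index[c("scenario", "prior_null")]))))
  agg <- stats::aggregate(fp_rate ~ scenario + prior_null, data = x$index,
                          FUN = stats::median)
  names(agg)[3] <- "median_fp_rate"
  print(agg, row.names = FALSE)
  invisible(x)
}
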