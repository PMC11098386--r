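# Aggregation of replicate runs into reported quantities: median
# trajectories, final-step false-positive-rate histograms, and pooled
# hypothesis-count / effort distributions.

#' Cumulative false-positive publication rate of a population
#'
#' Total false positives divided by total publications (true plus false
#' positives), summed over the living researchers only.  Agents without
#' publications contribute nothing to either sum.
#'
#' @param pop A `phack_population`.
#' @return Rate in `[0, 1]`, or `NA` (with a warning) when the population has
#'   no publications at all.
#' @export
cumulative_fp_rate <- function(pop) {
  total <- sum(pop$n_true_pos) + sum(pop$n_false_pos)
  if (total == 0L) {
    warning("population has no publications; cumulative FP rate is undefined",
            call. = FALSE)
    return(NA_real_)
  }
  sum(pop$n_false_pos) / total
}

grid_runs <- function(records) {
  if (inherits(records, "phack_grid")) records$runs
  else if (inherits(records, "phack_run")) list(records)
  else records
}

#' Replicate-averaged median trajectory
#'
#' For each time step, the recorded within-replicate median across living
#' agents is averaged (arithmetic mean) over replicates.
#'
#' @param records A `phack_grid`, a single `phack_run`, or a list of runs.
#'   Runs must share the same number of steps; mixing scenarios or priors is
#'   allowed but usually you want to subset first (see examples).
#' @param field One of `"median_effort"`, `"median_k"`, `"median_value"`,
#'   `"median_fp_frac"`, `"pooled_fp_rate"`.
#' @return data.frame with columns `step` and `value` (one row per step).
#' @examples
#' p <- phack_params(N = 50, n_steps = 20, n_replicates = 2)
#' g <- run_experiment_grid(p, scenarios = "single", priors = 0.8,
#'                          base_seed = 1)
#' head(median_trajectory(g, "median_k"))
#' @export
median_trajectory <- function(records, field = c("median_effort", "median_k",
                                                 "median_value",
                                                 "median_fp_frac",
                                                 "pooled_fp_rate")) {
  field <- match.arg(field)
  runs <- grid_runs(records)
  if (!length(runs)) stop("no runs supplied", call. = FALSE)
  steps <- vapply(runs, function(r) nrow(r$summary), integer(1))
  if (length(unique(steps)) != 1L) {
    stop("all runs must share the same number of steps", call. = FALSE)
  }
  mat <- vapply(runs, function(r) r$summary[[field]], numeric(steps[1]))
  mat <- matrix(mat, nrow = steps[1])
  data.frame(step = seq_len(steps[1]), value = rowMeans(mat, na.rm = TRUE))
}

hist_table <- function(x, breaks) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  data.frame(bin_lo = h$breaks[-length(h$breaks)],
             bin_hi = h$breaks[-1],
             count = h$counts)
}

#' Final-step distributions across replicates
#'
#' Builds the three end-of-run histograms: the replicate-level cumulative
#' false-positive rate (one value per replicate; replicates with zero
#' publications are excluded and counted), and the per-agent hypothesis-count
#' and effort distributions pooled over replicates and researchers.
#'
#' @param records A `phack_grid`, a single run, or a list of `phack_run`s.
#' @param fp_binwidth Bin width for the FP-rate histogram (default 0.025,
#'   fine enough to resolve a cluster between 0.875 and 0.9).
#' @param effort_binwidth Bin width for the effort histogram (default 10).
#' @return An object of class `phack_final_distributions`: list with
#'   `fp_rates` (the raw per-replicate rates), `fp_hist`, `k_hist` (unit-width
#'   integer bins), `effort_hist` (each a data.frame with `bin_lo`, `bin_hi`,
#'   `count`), and `n_undefined` (replicates excluded for having no
#'   publications).
#' @export
final_histograms <- function(records, fp_binwidth = 0.025,
                             effort_binwidth = 10) {
  runs <- grid_runs(records)
  if (!length(runs)) stop("no runs supplied", call. = FALSE)
  fp <- vapply(runs, function(r) r$fp_rate, numeric(1))
  n_undef <- sum(is.na(fp))
  fp <- fp[!is.na(fp)]
  k_all <- unlist(lapply(runs, function(r) r$final_population$k))
  e_all <- unlist(lapply(runs, function(r) r$final_population$effort))
  fp_breaks <- seq(0, 1 + fp_binwidth, by = fp_binwidth)
  k_breaks <- seq(min(k_all) - 0.5, max(k_all) + 0.5, by = 1)
  e_breaks <- seq(floor(min(e_all) / effort_binwidth) * effort_binwidth,
                  ceiling(max(e_all) / effort_binwidth) * effort_binwidth,
                  by = effort_binwidth)
  if (length(e_breaks) < 2L) e_breaks <- c(e_breaks, e_breaks + effort_binwidth)
  structure(
    list(fp_rates = unname(fp),
         fp_hist = if (length(fp)) hist_table(fp, fp_breaks) else
           data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)),
         k_hist = hist_table(k_all, k_breaks),
         effort_hist = hist_table(e_all, e_breaks),
         n_undefined = n_undef),
    class = "phack_final_distributions"
  )
}

#' @export
print.phack_final_distributions <- function(x, ...) {
  cat(sprintf(
    "<phack_final_distributions> %d replicates (%d with undefined FP rate)\n",
    length(x$fp_rates) + x$n_undefined, x$n_undefined))
  if (length(x$fp_rates)) {
    cat(sprintf("  replicate FP rate: median %.3f, range [%.3f, %.3f]\n",
                stats::median(x$fp_rates), min(x$fp_rates), max(x$fp_rates)))
  }
  invisible(x)
}

#' Mode of a binned replicate distribution
#'
#' Midpoint of the fullest histogram bin; ties resolve to the lowest bin.
#'
#' @param hist_df data.frame with `bin_lo`, `bin_hi`, `count` columns.
#' @return Numeric bin midpoint, or `NA` for an empty histogram.
#' @export
histogram_mode <- function(hist_df) {
  if (!nrow(hist_df) || !sum(hist_df$count)) return(NA_real_)
  i <- which.max(hist_df$count)
  (hist_df$bin_lo[i] + hist_df$bin_hi[i]) / 2
}
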