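# Configuration loading and output serialisation (CSV tables + JSON manifest).

#' Load a run configuration
#'
#' Reads an optional YAML file and applies programmatic overrides on top.
#' Recognised keys: any [phack_params()] field, plus `scenarios` (character
#' vector), `priors` (numeric vector), `preset` (`"full"` or `"reduced"`) and
#' `out_dir`.  Omitted parameters take the model defaults; the derived
#' effect-size scale `d0` is echoed via `message()`.
#'
#' @param path Path to a YAML configuration file, or `NULL`.
#' @param overrides Named list applied after (and over) the file contents.
#' @param quiet Suppress the configuration echo.
#' @return An object of class `phack_config`: list with `params`
#'   (a `phack_params`), `scenarios`, `priors`, `preset`, `out_dir`.
#' @examples
#' cfg <- load_config(overrides = list(prior_null = 0.8), quiet = TRUE)
#' cfg$params$d0
#' @export
load_config <- function(path = NULL, overrides = list(), quiet = FALSE) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  raw <- utils::modifyList(raw, overrides)
  meta_keys <- c("scenarios", "priors", "preset", "out_dir")
  unknown <- setdiff(names(raw), c(names(.param_defaults), meta_keys))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  preset <- raw$preset %||% "full"
  if (!preset %in% c("full", "reduced")) {
    stop("`preset` must be \"full\" or \"reduced\"", call. = FALSE)
  }
  param_over <- raw[intersect(names(raw), names(.param_defaults))]
  params <- do.call(preset_params, c(list(preset = preset), param_over))
  scenarios <- raw$scenarios %||% c("single", "multi_05", "multi_005")
  lapply(scenarios, as_scenario)  # validates names
  priors <- raw$priors %||% params$prior_null
  if (any(priors <= 0 | priors >= 1)) {
    stop("`priors` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!quiet) {
    message(sprintf(
      "config: preset %s, N = %d, %d steps x %d replicates; dmin = %g, prior_null = %g => d0 = %.4f",
      preset, params$N, params$n_steps, params$n_replicates,
      params$dmin, params$prior_null, params$d0))
  }
  structure(
    list(params = params, scenarios = as.character(scenarios),
         priors = as.numeric(priors), preset = preset,
         out_dir = raw$out_dir %||% "."),
    class = "phack_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    list(params = unclass(config$params), scenarios = config$scenarios,
         priors = config$priors, preset = config$preset),
    tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write grid outputs to disk
#'
#' For every (scenario, prior) cell writes
#' `trajectory_<scenario>_<prior>.csv` (columns `step`, `field`, `value`,
#' plus the embedded `config_hash` and `base_seed`) holding the
#' replicate-averaged median trajectories of all recorded fields, and
#' `final_hist_<scenario>_<prior>.csv` (columns `measure`, `bin_lo`,
#' `bin_hi`, `count`, `config_hash`, `base_seed`) holding the final-step
#' histograms.  A `manifest.json` records the full configuration, the hash,
#' the per-run seeds and the package version, so any cell can be re-run in
#' isolation and compared byte for byte.
#'
#' @param grid A `phack_grid` from [run_experiment_grid()].
#' @param dir Output directory (created if needed).
#' @param config The `phack_config` the grid was run from.
#' @return Invisibly, the paths written.
#' @export
write_grid_outputs <- function(grid, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  base_seed <- config$params$base_seed
  cells <- unique(grid$index[c("scenario", "prior_null")])
  paths <- character(0)
  fields <- c("median_effort", "median_k", "median_value", "median_fp_frac",
              "pooled_fp_rate")
  for (i in seq_len(nrow(cells))) {
    sc <- cells$scenario[i]
    pr <- cells$prior_null[i]
    keys <- grid$index$scenario == sc & grid$index$prior_null == pr
    runs <- grid$runs[which(keys)]
    traj <- do.call(rbind, lapply(fields, function(f) {
      tr <- median_trajectory(runs, f)
      data.frame(step = tr$step, field = f, value = tr$value)
    }))
    traj$config_hash <- hash
    traj$base_seed <- base_seed
    tpath <- file.path(dir, sprintf("trajectory_%s_%s.csv", sc, pr))
    utils::write.csv(traj, tpath, row.names = FALSE)

    fh <- final_histograms(runs)
    hist_df <- do.call(rbind, lapply(
      c(fp_rate = "fp_hist", k = "k_hist", effort = "effort_hist"),
      function(nm) fh[[nm]]))
    hist_df <- data.frame(
      measure = rep(c("fp_rate", "k", "effort"),
                    c(nrow(fh$fp_hist), nrow(fh$k_hist),
                      nrow(fh$effort_hist))),
      hist_df, config_hash = hash, base_seed = base_seed,
      row.names = NULL)
    hpath <- file.path(dir, sprintf("final_hist_%s_%s.csv", sc, pr))
    utils::write.csv(hist_df, hpath, row.names = FALSE)
    paths <- c(paths, tpath, hpath)
  }
  manifest <- list(
    package = "phacksim",
    version = as.character(utils::packageVersion("phacksim")),
    config_hash = hash,
    preset = config$preset,
    parameters = unclass(config$params),
    scenarios = config$scenarios,
    priors = config$priors,
    runs = grid$index)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mpath))
}
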