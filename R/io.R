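# Configuration and CSV input/output helpers.

#' Load a run configuration
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed) configuration
#' file and returns a validated run configuration. Recognised top-level keys:
#' `params` (model-parameter overrides, with `nprog` as a named map),
#' `settings` ([sim_settings()] fields), `mechanism` (an id string such as
#' `"ME+/CX-/EU"`), `space` (`lower`/`upper` named maps), `threshold`,
#' `n_samples`, `output_dir` and `scale` (`"desk"` or `"paper"`). Omitted
#' fields receive package defaults; unknown keys and invariant violations are
#' rejected with the offending key named.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list of class `"run_config"` with elements `params`, `settings`,
#'   `mechanism`, `space` (may be `NULL`), `threshold`, `n_samples`,
#'   `output_dir`, `scale`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configuration requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("params", "settings", "mechanism", "space", "threshold",
             "n_samples", "output_dir", "scale")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))

  pargs <- raw$params
  if (!is.null(pargs) && !is.null(pargs$nprog))
    pargs$nprog <- unlist(pargs$nprog)
  params <- do.call(model_params, as.list(pargs))
  settings <- do.call(sim_settings, as.list(raw$settings))
  mech <- mechanism(id = if (is.null(raw$mechanism)) "ME+/CX-/EU"
                    else raw$mechanism)
  space <- NULL
  if (!is.null(raw$space))
    space <- parameter_space(unlist(raw$space$lower),
                             unlist(raw$space$upper))
  scale <- if (is.null(raw$scale)) "desk" else
    match.arg(raw$scale, c("desk", "paper"))
  structure(list(
    params = params, settings = settings, mechanism = mech, space = space,
    threshold = if (is.null(raw$threshold)) 0.025 else raw$threshold,
    n_samples = if (is.null(raw$n_samples)) 500 else raw$n_samples,
    output_dir = raw$output_dir, scale = scale
  ), class = "run_config")
}

#' Persist the effective run configuration
#'
#' Writes a `"run_config"` back to JSON so a run's exact inputs can be
#' reloaded; `load_config(save_config(cfg, path))` round-trips.
#'
#' @param config A `"run_config"` from [load_config()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  p <- unclass(config$params)
  p$nprog <- as.list(p$nprog)
  out <- list(params = p, settings = unclass(config$settings),
              mechanism = config$mechanism$id,
              threshold = config$threshold, n_samples = config$n_samples,
              scale = config$scale)
  if (!is.null(config$space))
    out$space <- list(lower = as.list(config$space$lower),
                      upper = as.list(config$space$upper))
  if (!is.null(config$output_dir)) out$output_dir <- config$output_dir
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a trajectory set as CSV
#'
#' The CSV has columns `day`, `run_id` (run number, or `"mean"` / `"sd"` for
#' the aggregated rows), `live_count`, `cumulative_dead`, `frac_sox17`,
#' `frac_cxcr4` and the five per-phenotype fractions.
#'
#' @param ts A `"trajectory_set"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  cols <- c("live_count", "cumulative_dead", "frac_sox17", "frac_cxcr4",
            paste0("frac_", tolower(PHENOTYPES)))
  runs <- data.frame(day = ts$runs$day, run_id = as.character(ts$runs$run),
                     ts$runs[cols])
  s <- ts$summary
  mrow <- data.frame(day = s$day, run_id = "mean", s[cols])
  srow <- data.frame(day = s$day, run_id = "sd", s[paste0("sd_", cols)])
  names(srow) <- names(mrow)
  write.csv(rbind(runs, mrow, srow), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_endoderm_data
#' @export
read_endoderm_data <- function(path) {
  df <- read.csv(path)
  need <- c("day", "growth_norm", "death_norm", "frac_sox17", "frac_cxcr4")
  if (!all(need %in% names(df)))
    stop("dataset CSV must have columns: ", paste(need, collapse = ", "))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  structure(df[need],
            condition = meta$condition %||% NA_character_,
            noise_sd = meta$noise_sd %||% NA_real_,
            seed = meta$seed %||% NA_real_,
            provenance = meta$provenance %||% "file",
            class = c("endoderm_data", "data.frame"))
}

#' Write / read an endoderm induction dataset
#'
#' The dataset CSV holds the daily observables (`day`, `growth_norm`,
#' `death_norm`, `frac_sox17`, `frac_cxcr4`); a JSON sidecar
#' (`<path>.json`) records condition, noise level, seed and provenance.
#'
#' @param data An `"endoderm_data"` object.
#' @param path CSV output path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_endoderm_data <- function(data, path) {
  stopifnot(inherits(data, "endoderm_data"))
  write.csv(as.data.frame(data), path, row.names = FALSE)
  jsonlite::write_json(
    list(condition = attr(data, "condition"),
         noise_sd = attr(data, "noise_sd"), seed = attr(data, "seed"),
         provenance = attr(data, "provenance")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
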