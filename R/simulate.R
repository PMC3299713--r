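#' Simulate the differentiating cell population
#'
#' Runs the agent-based stochastic model: `settings$n_runs` independent
#' replicate runs of `settings$n_initial` cells over `settings$horizon` hours,
#' recording a snapshot every `settings$observation_interval` hours (daily by
#' default). Each replicate uses its own derived random stream, so the result
#' is a pure function of (params, mech, settings, seed), bit-identical across
#' repeated calls.
#'
#' Within each step every live cell undergoes, in order: affinity decay (Omega
#' only, with the `a_min` competence latch), regime transfer (G1-gated
#' Omega -> A with propensity averaging; A -> Omega), a lineage-propensity
#' update with commitment check (uncommitted cells in Omega/G1), then ageing,
#' death and cell-cycle-driven division. Cells in the A regime are quiescent.
#'
#' @param params A [model_params()].
#' @param mech A [mechanism()].
#' @param settings A [sim_settings()].
#' @param seed Master seed; defaults to `settings$seed`.
#' @param check_invariants If `TRUE`, the engine verifies the model invariants
#'   (conservation of cells, regime/affinity consistency, sub-threshold
#'   propensities) at every snapshot and aborts on violation. Useful in tests;
#'   slows the simulation down.
#' @param return_cells If `TRUE`, the initial and final cell tables of the
#'   first replicate run are returned (as data.frames) for inspection.
#'
#' @return An object of class `"trajectory_set"`: a list with elements
#'   `runs` (per-run, per-day data.frame of counts and fractions), `summary`
#'   (per-day mean and sd over runs of every observable), `params`, `mech`,
#'   `settings`, `extinct` (logical per run), `normalized` (flag: growth and
#'   death columns are raw counts, not day-4 normalised), and optionally
#'   `initial_cells` / `final_cells`.
#' @examples
#' ts <- simulate_population(model_params(), mechanism(id = "ME+/CX-/EU"),
#'                           sim_settings(n_initial = 200, n_runs = 4, seed = 7))
#' ts$summary[, c("day", "live_count", "frac_sox17", "frac_cxcr4")]
#' @export
simulate_population <- function(params, mech, settings, seed = settings$seed,
                                check_invariants = FALSE,
                                return_cells = FALSE) {
  stopifnot(inherits(params, "model_params"), inherits(mech, "mechanism"),
            inherits(settings, "sim_settings"))
  n_steps <- round(settings$horizon / params$dt)
  obs_every <- round(settings$observation_interval / params$dt)
  if (abs(n_steps * params$dt - settings$horizon) > 1e-9 ||
      abs(obs_every * params$dt - settings$observation_interval) > 1e-9)
    stop("horizon and observation_interval must be multiples of dt")

  s1 <- lineage_slots(1, mech)
  s1_phen <- match(s1, PHENOTYPES) - 1L
  s1_nprog <- nprog_slots(params, 1, mech)
  s2_phen <- match(c("DEFINITIVE_ENDODERM", "MESODERM"), PHENOTYPES) - 1L
  s2_nprog <- nprog_slots(params, 2, mech)
  prolif <- proliferation_allowed(PHENOTYPES, mech)

  res <- .sim_engine(settings$n_initial, settings$n_runs, n_steps, obs_every,
                     params$a_min, params$a_0max, params$a_0max2,
                     params$x_com, params$x_com2, params$d, params$t_g1,
                     params$t_cycle, params$l_min, params$l_max,
                     params$w_max, params$aa, params$n_scale, params$dt,
                     s1_phen, s1_nprog, s2_phen, s2_nprog, prolif,
                     as.numeric(seed), check_invariants, return_cells)
  if (any(res$extinct))
    warning(sum(res$extinct), " run(s) went extinct before the horizon; ",
            "remaining observations zero-filled")

  runs <- as.data.frame(res$trajectories)
  names(runs)[names(runs) == "n_hesc"] <- "n_HESC"
  names(runs)[names(runs) == "n_mesendoderm"] <- "n_MESENDODERM"
  names(runs)[names(runs) == "n_visceral_endoderm"] <- "n_VISCERAL_ENDODERM"
  names(runs)[names(runs) == "n_definitive_endoderm"] <- "n_DEFINITIVE_ENDODERM"
  names(runs)[names(runs) == "n_mesoderm"] <- "n_MESODERM"

  cnt <- as.matrix(runs[, paste0("n_", PHENOTYPES)])
  colnames(cnt) <- PHENOTYPES
  live <- runs$live_count
  pos <- live > 0
  fr <- matrix(NA_real_, nrow(runs), 7,
               dimnames = list(NULL, c(paste0("frac_", tolower(PHENOTYPES)),
                                       "frac_sox17", "frac_cxcr4")))
  if (any(pos)) {
    fr[pos, 1:5] <- cnt[pos, , drop = FALSE] / live[pos]
    mk <- marker_fractions(cnt[pos, , drop = FALSE], mech)
    fr[pos, "frac_sox17"] <- mk$frac_sox17
    fr[pos, "frac_cxcr4"] <- mk$frac_cxcr4
  }
  runs <- cbind(runs, as.data.frame(fr))

  obs_cols <- setdiff(names(runs), c("run", "day"))
  agg_mean <- aggregate(runs[obs_cols], by = list(day = runs$day),
                        FUN = mean, na.rm = TRUE)
  agg_sd <- aggregate(runs[obs_cols], by = list(day = runs$day),
                      FUN = function(v) if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0)
  names(agg_sd)[-1] <- paste0("sd_", names(agg_sd)[-1])
  smry <- merge(agg_mean, agg_sd, by = "day")
  smry <- smry[order(smry$day), ]
  rownames(smry) <- NULL

  out <- list(runs = runs, summary = smry, params = params, mech = mech,
              settings = settings, seed = as.numeric(seed),
              extinct = as.logical(res$extinct), normalized = FALSE)
  if (return_cells) {
    out$initial_cells <- cells_from_engine(res$initial_cells)
    out$final_cells <- cells_from_engine(res$final_cells)
  }
  class(out) <- "trajectory_set"
  out
}

#' Simulate a single replicate run
#'
#' Convenience wrapper around [simulate_population()] with `n_runs = 1`;
#' returns the per-day data.frame of that run.
#'
#' @inheritParams simulate_population
#' @return A data.frame with one row per observation day.
#' @export
simulate_run <- function(params, mech, settings, seed = settings$seed, ...) {
  settings$n_runs <- 1L
  simulate_population(params, mech, settings, seed = seed, ...)$runs
}

#' @export
print.trajectory_set <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Trajectory set: mechanism %s, %d runs x %d initial cells, days %g-%g\n",
    x$mech$id, s$n_runs, s$n_initial, min(x$summary$day), max(x$summary$day)))
  cols <- c("day", "live_count", "cumulative_dead", "frac_sox17", "frac_cxcr4",
            "frac_hesc")
  print(cbind(x$summary[cols[1]], signif(x$summary[cols[-1]], 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) x$runs

#' @export
plot.trajectory_set <- function(x, ...) {
  s <- x$summary
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  band <- function(y, sdv, main, ylab) {
    ylim <- range(c(y - sdv, y + sdv), na.rm = TRUE)
    plot(s$day, y, type = "l", lwd = 2, ylim = ylim, xlab = "day",
         ylab = ylab, main = main)
    polygon(c(s$day, rev(s$day)), c(y - sdv, rev(y + sdv)),
            col = adjustcolor("grey40", 0.3), border = NA)
    lines(s$day, y, lwd = 2)
  }
  band(s$live_count, s$sd_live_count, "Cellular growth", "live cells")
  band(s$cumulative_dead, s$sd_cumulative_dead, "Cell death",
       "cumulative dead")
  band(s$frac_sox17, s$sd_frac_sox17, "Sox17+", "fraction")
  band(s$frac_cxcr4, s$sd_frac_cxcr4, "CXCR4+", "fraction")
  invisible(x)
}
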