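#' Model parameters of the stochastic differentiation model
#'
#' Constructs and validates the parameter vector of the population-based
#' model. Each cell carries an affinity `a` for the quiescent signalling
#' regime A; `a` is drawn uniformly on `(0, a_0max]` at birth of the
#' simulation, decays geometrically (`a <- a / d` per step) while the cell is
#' in the active regime Omega, and is frozen in A. Once `a` first falls below
#' `a_min` the cell permanently loses the ability to enter A and becomes
#' proliferation-competent. Commitment to a lineage occurs when that lineage's
#' propensity reaches the stage threshold (`x_com` for stage 1, `x_com2` for
#' stage 2, i.e. after mesendoderm commitment).
#'
#' @param a_min Affinity threshold: below it a cell can no longer enter the A
#'   regime and becomes able to proliferate. Dimensionless.
#' @param a_0max Upper bound of the initial affinity draw (stage 1).
#' @param a_0max2 Upper bound of the affinity re-draw after mesendoderm
#'   commitment (stage 2).
#' @param x_com Stage-1 lineage-propensity commitment threshold.
#' @param x_com2 Stage-2 commitment threshold (mesendoderm to definitive
#'   endoderm / mesoderm).
#' @param d Per-step affinity decay factor, must exceed 1.
#' @param t_g1 Duration of the G1 phase of the cell cycle, hours. Only in G1
#'   can a cell update lineage propensities or transfer Omega -> A.
#' @param t_cycle Total cell-cycle duration, hours.
#' @param l_min,l_max Bounds of the uniform lifespan assignment, hours.
#' @param w_max Upper bound of the uniform proliferation-window assignment,
#'   hours (time a competent cell may keep dividing before senescence).
#' @param aa Scale factor of the Omega -> A transfer probability.
#' @param n_scale Population scale of the crowding function
#'   `f(N) = 1 / (1 + N / n_scale)` applied to the destination-regime count.
#' @param dt Simulation time step, hours.
#' @param nprog Named numeric vector of propensity-update magnitude factors,
#'   one per reachable lineage and stage: `me`, `ve`, `de`, `meso` (stage 1)
#'   and `de2`, `meso2` (stage 2). Non-negative.
#' @param ... Named overrides applied on top of the defaults, e.g.
#'   `model_params(d = 1.1)`.
#'
#' @return An object of class `"model_params"` (a validated named list).
#' @examples
#' p <- model_params(d = 1.08, aa = 0.3)
#' p$d
#' @export
model_params <- function(a_min = 0.1, a_0max = 1, a_0max2 = 0.5,
                         x_com = 1, x_com2 = 1, d = 1.04,
                         t_g1 = 12, t_cycle = 32,
                         l_min = 24, l_max = 200, w_max = 72,
                         aa = 0.5, n_scale = 1000, dt = 1,
                         nprog = c(me = 6, ve = 4, de = 4, meso = 4,
                                   de2 = 6, meso2 = 8), ...) {
  extra <- list(...)
  p <- list(a_min = a_min, a_0max = a_0max, a_0max2 = a_0max2,
            x_com = x_com, x_com2 = x_com2, d = d,
            t_g1 = t_g1, t_cycle = t_cycle,
            l_min = l_min, l_max = l_max, w_max = w_max,
            aa = aa, n_scale = n_scale, dt = dt, nprog = nprog)
  if (length(extra)) {
    bad <- setdiff(names(extra), names(p))
    if (length(bad) || is.null(names(extra)) || any(names(extra) == ""))
      stop("unknown model parameter(s): ", paste(bad, collapse = ", "))
    p <- modifyList(p, extra)
  }
  validate_model_params(p)
}

validate_model_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(key) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", key, "' must be a single finite number")
    v
  }
  chk <- function(ok, msg) if (!ok) stop("invalid model parameters: ", msg)
  chk(num1("a_min") > 0, "a_min must be > 0")
  chk(num1("a_0max") > p$a_min, "a_min must be < a_0max")
  chk(num1("a_0max2") > 0, "a_0max2 must be > 0")
  chk(num1("x_com") > 0, "x_com must be > 0")
  chk(num1("x_com2") > 0, "x_com2 must be > 0")
  chk(num1("d") > 1, "d must be > 1")
  chk(num1("t_g1") > 0 && p$t_g1 <= num1("t_cycle"),
      "t_g1 must satisfy 0 < t_g1 <= t_cycle")
  chk(num1("l_min") >= 0 && num1("l_max") > p$l_min,
      "lifespan bounds must satisfy 0 <= l_min < l_max")
  chk(num1("w_max") > 0, "w_max must be > 0")
  chk(num1("aa") >= 0, "aa must be >= 0")
  chk(num1("n_scale") > 0, "n_scale must be > 0")
  chk(num1("dt") > 0, "dt must be > 0")
  np <- p$nprog
  need <- c("me", "ve", "de", "meso", "de2", "meso2")
  if (!is.numeric(np) || is.null(names(np)) || !all(need %in% names(np)))
    stop("invalid model parameters: nprog must be a named numeric vector ",
         "with entries ", paste(need, collapse = ", "))
  chk(all(is.finite(np)) && all(np >= 0), "all nprog entries must be >= 0")
  p$nprog <- np[need]
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (stochastic hESC differentiation model)\n")
  sc <- x[setdiff(names(x), "nprog")]
  cat(paste0("  ", format(names(sc), width = 8), " = ",
             vapply(sc, format, ""), collapse = "\n"), "\n")
  cat("  nprog    =", paste(names(x$nprog), signif(x$nprog, 4), sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Simulation settings
#'
#' Run-level settings of the stochastic simulation: how many cells to start
#' from, how many independent replicate runs to average, how long to simulate
#' and how often to record observations.
#'
#' @param n_initial Initial number of cells (all undifferentiated hESC, all in
#'   the Omega regime).
#' @param n_runs Number of independent stochastic replicate runs.
#' @param horizon Simulated time, hours; must be a positive multiple of
#'   `observation_interval`. Default 120 h (days 0-5).
#' @param observation_interval Hours between recorded snapshots; default 24.
#' @param seed Integer master seed. Every replicate run receives its own
#'   derived, independent random stream, so results are reproducible and
#'   independent of execution order.
#'
#' @return An object of class `"sim_settings"`.
#' @examples
#' sim_settings(n_initial = 500, n_runs = 10, seed = 42)
#' @export
sim_settings <- function(n_initial = 1000, n_runs = 100, horizon = 120,
                         observation_interval = 24, seed = 1) {
  s <- list(n_initial = as.integer(n_initial), n_runs = as.integer(n_runs),
            horizon = horizon, observation_interval = observation_interval,
            seed = as.numeric(seed))
  chk <- function(ok, msg) if (!ok) stop("invalid simulation settings: ", msg)
  chk(s$n_initial >= 1L, "n_initial must be >= 1")
  chk(s$n_runs >= 1L, "n_runs must be >= 1")
  chk(s$horizon > 0 && s$observation_interval > 0 &&
        abs(s$horizon / s$observation_interval -
              round(s$horizon / s$observation_interval)) < 1e-9,
      "horizon must be a positive multiple of observation_interval")
  chk(is.finite(s$seed) && s$seed >= 0, "seed must be a non-negative number")
  structure(s, class = "sim_settings")
}

#' @export
print.sim_settings <- function(x, ...) {
  cat(sprintf(
    "Simulation settings: %d initial cells, %d runs, %g h horizon (obs every %g h), seed %s\n",
    x$n_initial, x$n_runs, x$horizon, x$observation_interval,
    format(x$seed)), sep = "")
  invisible(x)
}
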