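#' Parameter hyper-space for ensemble sampling
#'
#' Defines, per sampled parameter, a finite lower and upper bound; all other
#' model parameters are held fixed at their nominal values. Entries of the
#' `nprog` vector are addressed with a `nprog_` prefix (e.g. `nprog_me`).
#'
#' @param lower,upper Named numeric vectors with identical names; each lower
#'   bound strictly below its upper bound.
#' @return An object of class `"parameter_space"`.
#' @examples
#' parameter_space(c(d = 1.01, aa = 0.05), c(d = 1.25, aa = 2))
#' @export
parameter_space <- function(lower, upper) {
  if (is.null(names(lower)) || is.null(names(upper)) ||
      !identical(names(lower), names(upper)))
    stop("lower and upper must be named identically")
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("parameter-space bounds must be finite")
  if (!all(lower < upper))
    stop("each lower bound must be strictly below its upper bound: ",
         paste(names(lower)[lower >= upper], collapse = ", "))
  structure(list(lower = lower, upper = upper, names = names(lower)),
            class = "parameter_space")
}

#' Default sampling bounds for the sensitive parameters
#'
#' Bounds around the documented nominal values for the parameter classes that
#' drive the model output: affinity thresholds and bounds, decay factor, G1
#' duration, lifespan upper bound, transfer scale and the propensity-update
#' magnitudes of the lineages reachable under the mechanism. The commitment
#' thresholds `x_com`/`x_com2` are not sampled: under the propensity-update
#' rule the increments scale with the threshold, so the thresholds cancel out
#' of the dynamics and the `nprog` magnitudes carry those degrees of freedom.
#'
#' @param mech A [mechanism()]; mechanisms without mesendoderm have no
#'   stage-2 parameters and sample the single-stage `nprog` entries instead.
#' @param params Nominal [model_params()] the bounds are centred on.
#' @details Bounds span one order of magnitude either side of the nominal
#'   value, capped where a hard invariant demands it: `d` is expanded on the
#'   decay-rate scale `d - 1` (so it stays above 1), `t_g1` is capped at
#'   `t_cycle`, and `l_max` stays above `l_min`. Sampled combinations that
#'   still violate a joint invariant (e.g. `a_min >= a_0max`) are rejected
#'   with infinite error during fitting.
#' @return A [parameter_space()].
#' @export
default_parameter_space <- function(mech, params = model_params()) {
  stopifnot(inherits(mech, "mechanism"))
  dec <- function(v) c(v / 10, v * 10)
  lo <- c(a_min = params$a_min / 10, a_0max = params$a_0max / 10,
          d = 1 + (params$d - 1) / 10,
          t_g1 = params$t_g1 / 10,
          l_max = max(params$l_max / 10, params$l_min + params$dt),
          aa = params$aa / 10, nprog_ve = params$nprog[["ve"]] / 10)
  hi <- c(a_min = params$a_min * 10, a_0max = params$a_0max * 10,
          d = 1 + (params$d - 1) * 10,
          t_g1 = min(params$t_g1 * 10, params$t_cycle),
          l_max = params$l_max * 10,
          aa = params$aa * 10, nprog_ve = params$nprog[["ve"]] * 10)
  if (mech$include_mesendoderm) {
    lo <- c(lo, a_0max2 = params$a_0max2 / 10,
            nprog_me = params$nprog[["me"]] / 10,
            nprog_de2 = params$nprog[["de2"]] / 10,
            nprog_meso2 = params$nprog[["meso2"]] / 10)
    hi <- c(hi, a_0max2 = params$a_0max2 * 10,
            nprog_me = params$nprog[["me"]] * 10,
            nprog_de2 = params$nprog[["de2"]] * 10,
            nprog_meso2 = params$nprog[["meso2"]] * 10)
  } else {
    lo <- c(lo, nprog_de = params$nprog[["de"]] / 10,
            nprog_meso = params$nprog[["meso"]] / 10)
    hi <- c(hi, nprog_de = params$nprog[["de"]] * 10,
            nprog_meso = params$nprog[["meso"]] * 10)
  }
  parameter_space(lo, hi)
}

#' Draw random parameter samples from a space
#'
#' Independent uniform draws per dimension, reproducible under `seed`.
#'
#' @param space A [parameter_space()].
#' @param n_samples Number of samples (rows).
#' @param seed RNG seed.
#' @return Numeric matrix `n_samples x n_parameters` with named columns.
#' @export
sample_parameter_space <- function(space, n_samples, seed = 1) {
  stopifnot(inherits(space, "parameter_space"), n_samples >= 1)
  set.seed(seed)
  p <- length(space$names)
  m <- matrix(runif(n_samples * p), n_samples, p)
  m <- sweep(m, 2, space$upper - space$lower, "*")
  m <- sweep(m, 2, space$lower, "+")
  colnames(m) <- space$names
  m
}

# Overlay one sampled row onto a model_params object (nprog_ prefixed names
# address nprog entries) and revalidate.
apply_sample <- function(params, row) {
  p <- unclass(params)
  for (nm in names(row)) {
    if (startsWith(nm, "nprog_")) {
      p$nprog[[sub("^nprog_", "", nm)]] <- row[[nm]]
    } else {
      p[[nm]] <- row[[nm]]
    }
  }
  validate_model_params(p)
}

#' Least-squares error between simulated and observed marker dynamics
#'
#' The fitting criterion: the mean squared residual of the Sox17+ and CXCR4+
#' fractions over the shared observation days,
#' `error = (1/(2T)) * sum_days [ (sox17_sim - sox17_obs)^2 +
#' (cxcr4_sim - cxcr4_obs)^2 ]` with fractions on the 0-1 scale. Growth and
#' death curves are deliberately excluded: they serve as post-fit
#' verification, never as fitting targets. The error is invariant to any
#' rescaling of the simulated live counts.
#'
#' @param sim A `"trajectory_set"` (its per-day mean fractions are used) or a
#'   data.frame with columns `day`, `frac_sox17`, `frac_cxcr4`.
#' @param data An [generate_calibration_data()]-style dataset covering the
#'   same observation days.
#' @return A single non-negative number (`Inf` if the simulation lost its
#'   population and fractions are undefined).
#' @examples
#' d <- generate_calibration_data("A")
#' trajectory_error(d, d)  # 0
#' @export
trajectory_error <- function(sim, data) {
  s <- if (inherits(sim, "trajectory_set")) sim$summary else sim
  idx <- match(data$day, s$day)
  if (anyNA(idx))
    stop("simulation and data observation days do not align")
  ds <- s$frac_sox17[idx] - data$frac_sox17
  dc <- s$frac_cxcr4[idx] - data$frac_cxcr4
  if (anyNA(ds) || anyNA(dc)) return(Inf)
  mean(ds^2 + dc^2) / 2
}

# day-4 normalised growth/death verification score of a simulated summary
verification_score <- function(s, data) {
  idx <- match(data$day, s$day)
  i4 <- match(4, s$day)
  if (anyNA(idx) || is.na(i4)) return(NA_real_)
  if (s$live_count[i4] <= 0 || s$cumulative_dead[i4] <= 0) return(NA_real_)
  dg <- s$live_count[idx] / s$live_count[i4] - data$growth_norm
  dd <- s$cumulative_dead[idx] / s$cumulative_dead[i4] - data$death_norm
  mean(dg^2 + dd^2) / 2
}

#' Ensemble parameter estimation for one mechanism
#'
#' The model-fitting workhorse: draws `n_samples` random parameter vectors
#' from `space`, simulates each under `mech`, scores each against the
#' observed Sox17/CXCR4 marker dynamics with [trajectory_error()], and
#' retains the ensemble of parameter sets whose error does not exceed
#' `threshold`, together with the best-fitting set. All samples share the
#' same replicate random streams (common random numbers), so differences in
#' error reflect parameters, not Monte-Carlo noise, and re-simulating the
#' best sample reproduces its fitted trajectories exactly.
#'
#' @param data Observed dataset (an `"endoderm_data"` object or data.frame
#'   with columns `day`, `growth_norm`, `death_norm`, `frac_sox17`,
#'   `frac_cxcr4`).
#' @param mech A [mechanism()].
#' @param settings A [sim_settings()]; `n_runs` and `n_initial` set the
#'   per-sample simulation scale.
#' @param space A [parameter_space()]; defaults to
#'   [default_parameter_space()] for the mechanism.
#' @param n_samples Number of random parameter samples.
#' @param threshold Acceptance threshold on the ensemble error.
#' @param seed Master seed for sampling and simulation.
#' @param base_params Nominal [model_params()] supplying every parameter not
#'   in `space`.
#' @return An object of class `"endoderm_fit"` with components `samples`
#'   (matrix), `errors`, `accepted` (logical mask), `best_index`,
#'   `best_params`, `best_error`, `best_trajectory` (a `"trajectory_set"`),
#'   `envelope` (per-day min/max over the accepted ensemble for growth,
#'   death, Sox17 and CXCR4), `verification` (growth/death score of the best
#'   fit), plus the call ingredients and a `meta` record of the scale used.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
#'   `simulate`.
#' @seealso [rank_mechanisms()] to compare all twelve mechanisms.
#' @export
fit_ensemble <- function(data, mech, settings,
                         space = default_parameter_space(mech),
                         n_samples = 500, threshold = 0.025, seed = 1,
                         base_params = model_params()) {
  stopifnot(inherits(mech, "mechanism"), inherits(settings, "sim_settings"),
            inherits(space, "parameter_space"))
  samples <- sample_parameter_space(space, n_samples, seed = seed)
  errors <- numeric(n_samples)
  days <- data$day
  nd <- length(days)
  traj <- list(growth = matrix(NA_real_, n_samples, nd),
               death = matrix(NA_real_, n_samples, nd),
               sox17 = matrix(NA_real_, n_samples, nd),
               cxcr4 = matrix(NA_real_, n_samples, nd))
  for (i in seq_len(n_samples)) {
    pi <- tryCatch(apply_sample(base_params, samples[i, ]),
                   error = function(e) NULL)
    if (is.null(pi)) {  # sampled combination violates an invariant
      errors[i] <- Inf
      next
    }
    ts <- withCallingHandlers(
      simulate_population(pi, mech, settings, seed = seed),
      warning = function(w) invokeRestart("muffleWarning"))
    errors[i] <- trajectory_error(ts, data)
    s <- ts$summary
    idx <- match(days, s$day)
    i4 <- match(4, s$day)
    traj$growth[i, ] <- if (!is.na(i4) && s$live_count[i4] > 0)
      s$live_count[idx] / s$live_count[i4] else NA_real_
    traj$death[i, ] <- if (!is.na(i4) && s$cumulative_dead[i4] > 0)
      s$cumulative_dead[idx] / s$cumulative_dead[i4] else NA_real_
    traj$sox17[i, ] <- s$frac_sox17[idx]
    traj$cxcr4[i, ] <- s$frac_cxcr4[idx]
  }
  accepted <- is.finite(errors) & errors <= threshold
  if (!any(accepted))
    warning("no parameter sample met the error threshold ", threshold,
            " (minimum error ", signif(min(errors), 3), ")")
  best_index <- which.min(errors)
  best_params <- apply_sample(base_params, samples[best_index, ])
  best_trajectory <- simulate_population(best_params, mech, settings,
                                         seed = seed)
  env <- NULL
  if (any(accepted)) {
    env <- data.frame(day = days)
    for (out in names(traj)) {
      m <- traj[[out]][accepted, , drop = FALSE]
      env[[paste0(out, "_min")]] <- suppressWarnings(apply(m, 2, min, na.rm = TRUE))
      env[[paste0(out, "_max")]] <- suppressWarnings(apply(m, 2, max, na.rm = TRUE))
    }
  }
  structure(list(
    samples = samples, errors = errors, accepted = accepted,
    threshold = threshold, best_index = best_index,
    best_params = best_params, best_error = errors[best_index],
    best_trajectory = best_trajectory,
    envelope = env, data = data, mech = mech, settings = settings,
    space = space, seed = seed, base_params = base_params,
    verification = verification_score(best_trajectory$summary, data),
    meta = list(n_samples = n_samples, n_runs = settings$n_runs,
                n_initial = settings$n_initial,
                scale = if (n_samples >= 10000 && settings$n_runs >= 4000)
                  "paper" else "scaled-down")
  ), class = "endoderm_fit")
}

#' @export
print.endoderm_fit <- function(x, ...) {
  cat(sprintf(
    "Ensemble fit, mechanism %s (%s scale: %d samples x %d runs x %d cells)\n",
    x$mech$id, x$meta$scale, x$meta$n_samples, x$meta$n_runs,
    x$meta$n_initial))
  cat(sprintf("  best error %.4g; %d/%d samples accepted at threshold %g\n",
              x$best_error, sum(x$accepted), length(x$errors), x$threshold))
  cat(sprintf("  growth/death verification score %.4g\n", x$verification))
  invisible(x)
}

#' @export
summary.endoderm_fit <- function(object, ...) {
  print(object)
  cat("Best-fit sampled parameters:\n")
  print(signif(coef(object), 4))
  if (any(object$accepted)) {
    acc <- object$samples[object$accepted, , drop = FALSE]
    cat("Accepted-ensemble parameter ranges:\n")
    print(signif(t(apply(acc, 2, range)), 3))
  }
  invisible(object)
}

#' @export
coef.endoderm_fit <- function(object, ...) {
  object$samples[object$best_index, ]
}

#' Best-fit predicted trajectories
#'
#' Returns the per-day mean trajectories simulated at the best-fit
#' parameters: counts, phenotype fractions (including the undifferentiated
#' hESC fraction) and marker fractions.
#'
#' @param object An `"endoderm_fit"`.
#' @param ... Unused.
#' @return Data.frame, one row per observation day.
#' @export
predict.endoderm_fit <- function(object, ...) {
  object$best_trajectory$summary
}

#' @export
residuals.endoderm_fit <- function(object, ...) {
  s <- object$best_trajectory$summary
  idx <- match(object$data$day, s$day)
  data.frame(day = object$data$day,
             sox17 = s$frac_sox17[idx] - object$data$frac_sox17,
             cxcr4 = s$frac_cxcr4[idx] - object$data$frac_cxcr4)
}

#' Re-simulate the best-fit model
#'
#' @param object An `"endoderm_fit"`.
#' @param nsim Number of replicate runs (defaults to the fit's settings).
#' @param seed Master seed for the new simulation.
#' @param ... Unused.
#' @return A `"trajectory_set"`.
#' @export
simulate.endoderm_fit <- function(object, nsim = NULL, seed = NULL, ...) {
  st <- object$settings
  if (!is.null(nsim)) st$n_runs <- as.integer(nsim)
  if (is.null(seed)) seed <- object$seed
  simulate_population(object$best_params, object$mech, st, seed = seed)
}

#' @export
plot.endoderm_fit <- function(x, ...) {
  d <- x$data
  env <- x$envelope
  s <- x$best_trajectory$summary
  idx <- match(d$day, s$day)
  i4 <- match(4, s$day)
  best <- list(growth = s$live_count[idx] / s$live_count[i4],
               death = s$cumulative_dead[idx] /
                 max(s$cumulative_dead[i4], 1e-12),
               sox17 = s$frac_sox17[idx], cxcr4 = s$frac_cxcr4[idx])
  obs <- list(growth = d$growth_norm, death = d$death_norm,
              sox17 = d$frac_sox17, cxcr4 = d$frac_cxcr4)
  titles <- c(growth = "Growth (day-4 norm.)", death = "Death (day-4 norm.)",
              sox17 = "Sox17+ fraction", cxcr4 = "CXCR4+ fraction")
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (out in names(titles)) {
    lo <- if (!is.null(env)) env[[paste0(out, "_min")]] else best[[out]]
    hi <- if (!is.null(env)) env[[paste0(out, "_max")]] else best[[out]]
    ylim <- range(c(lo, hi, obs[[out]], best[[out]]), na.rm = TRUE)
    plot(d$day, obs[[out]], pch = 16, ylim = ylim, xlab = "day",
         ylab = out, main = titles[[out]])
    if (!is.null(env))
      polygon(c(d$day, rev(d$day)), c(lo, rev(hi)),
              col = adjustcolor("grey50", 0.35), border = NA)
    lines(d$day, best[[out]], lwd = 2)
    points(d$day, obs[[out]], pch = 16)
  }
  invisible(x)
}

#' Rank candidate mechanisms by minimum ensemble error
#'
#' Runs [fit_ensemble()] for every supplied mechanism against the same
#' dataset and reports the per-mechanism minimum error together with the
#' growth/death verification score of each best fit (verification is
#' reported, never fitted).
#'
#' @param data Observed dataset (see [fit_ensemble()]).
#' @param settings A [sim_settings()].
#' @param mechanisms List of [mechanism()] objects; defaults to all twelve.
#' @param spaces Optional named list of [parameter_space()]s per mechanism
#'   id; defaults to [default_parameter_space()] for each.
#' @param n_samples,threshold,seed Passed to [fit_ensemble()].
#' @param base_params Nominal [model_params()].
#' @param keep_fits If `TRUE`, attach the individual `"endoderm_fit"`
#'   objects as attribute `fits`.
#' @return An object of class `"mechanism_ranking"`: a data.frame sorted by
#'   minimum error, with columns `id`, `include_mesendoderm`,
#'   `cxcr4_in_mesoderm`, `proliferation_scope`, `min_error`, `n_accepted`,
#'   `verification`.
#' @export
rank_mechanisms <- function(data, settings,
                            mechanisms = enumerate_mechanisms(),
                            spaces = NULL, n_samples = 200,
                            threshold = 0.025, seed = 1,
                            base_params = model_params(),
                            keep_fits = FALSE) {
  fits <- lapply(mechanisms, function(m) {
    sp <- if (!is.null(spaces) && !is.null(spaces[[m$id]])) spaces[[m$id]]
          else default_parameter_space(m)
    withCallingHandlers(
      fit_ensemble(data, m, settings, space = sp, n_samples = n_samples,
                   threshold = threshold, seed = seed,
                   base_params = base_params),
      warning = function(w) invokeRestart("muffleWarning"))
  })
  tab <- data.frame(
    id = vapply(mechanisms, `[[`, "", "id"),
    include_mesendoderm = vapply(mechanisms, `[[`, TRUE,
                                 "include_mesendoderm"),
    cxcr4_in_mesoderm = vapply(mechanisms, `[[`, TRUE, "cxcr4_in_mesoderm"),
    proliferation_scope = vapply(mechanisms, `[[`, "", "proliferation_scope"),
    min_error = vapply(fits, `[[`, 0, "best_error"),
    n_accepted = vapply(fits, function(f) sum(f$accepted), 0L),
    verification = vapply(fits, `[[`, 0, "verification"))
  tab <- tab[order(tab$min_error), ]
  rownames(tab) <- NULL
  out <- structure(tab, class = c("mechanism_ranking", "data.frame"))
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' @export
print.mechanism_ranking <- function(x, ...) {
  cat("Mechanism ranking by minimum ensemble error:\n")
  y <- as.data.frame(x)
  y$min_error <- signif(y$min_error, 4)
  y$verification <- signif(y$verification, 4)
  print(y[, c("id", "min_error", "n_accepted", "verification")],
        row.names = FALSE)
  invisible(x)
}
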