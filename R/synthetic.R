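#' Synthetic calibration time courses for the two induction conditions
#'
#' Generates the daily (days 0-5) calibration dataset the fitting pipeline
#' consumes, emulating the qualitative features of the experimental induction
#' time courses: Condition A (Activin A) shows a proliferation lag with a mild
#' decline in live cells up to day 3 followed by roughly linear growth, while
#' under Condition B (Activin A + FGF2 + BMP4) the majority of growth occurs
#' before day 3. Cumulative cell death is linear in time for both. The Sox17+
#' fraction follows a concave quadratic through zero at day 0 peaking at
#' `sox17_peak` on day `sox17_peak_day` (A: 0.19 at day 3; B: 0.23 at day 2,
#' within the observed 19-23% / days 2-3 window). The CXCR4+ fraction is flat
#' at `cxcr4_plateau` until day 2, drops to `cxcr4_low` (day-3 sample), then
#' rises linearly with slope `cxcr4_slope` per day — steeper for Condition B.
#'
#' Growth and cumulative death are reported normalised to their day-4 value.
#' With `noise_sd > 0`, Gaussian noise is added per point and the curves are
#' clipped back to their valid ranges (fractions to `[0, 1]`, growth
#' non-negative, death non-decreasing and re-normalised at day 4).
#'
#' @param condition `"A"` (Activin A) or `"B"` (Activin A + FGF2 + BMP4).
#' @param noise_sd Standard deviation of additive Gaussian measurement noise
#'   (0 = deterministic nominal curves).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param sox17_peak,sox17_peak_day Peak Sox17+ fraction and its day.
#' @param cxcr4_plateau,cxcr4_low,cxcr4_slope CXCR4+ curve configuration.
#' @param growth Length-6 vector of raw live-cell counts (relative units) for
#'   days 0-5, normalised internally to day 4.
#' @return An object of class `"endoderm_data"`: a data.frame with columns
#'   `day`, `growth_norm`, `death_norm`, `frac_sox17`, `frac_cxcr4` and
#'   attributes `condition`, `noise_sd`, `seed`, `provenance`
#'   (`"calibration"`).
#' @examples
#' d <- generate_calibration_data("A")
#' max(d$frac_sox17)  # 0.19, at day 3
#' @export
generate_calibration_data <- function(condition = c("A", "B"), noise_sd = 0,
                                      seed = 1,
                                      sox17_peak = NULL, sox17_peak_day = NULL,
                                      cxcr4_plateau = 0.10, cxcr4_low = NULL,
                                      cxcr4_slope = NULL, growth = NULL) {
  condition <- match.arg(condition)
  stopifnot(noise_sd >= 0)
  days <- 0:5
  if (is.null(sox17_peak)) sox17_peak <- if (condition == "A") 0.19 else 0.23
  if (is.null(sox17_peak_day)) sox17_peak_day <- if (condition == "A") 3 else 2
  if (is.null(cxcr4_low)) cxcr4_low <- if (condition == "A") 0.05 else 0.03
  if (is.null(cxcr4_slope)) cxcr4_slope <- if (condition == "A") 0.12 else 0.20
  if (is.null(growth))
    growth <- if (condition == "A") c(1.00, 0.95, 0.90, 0.85, 1.05, 1.25)
              else c(1.00, 1.30, 1.70, 2.00, 2.15, 2.25)
  stopifnot(length(growth) == 6)

  growth_norm <- growth / growth[5]
  death_norm <- days / 4
  sox17 <- pmax(0, pmin(1, sox17_peak *
                          (1 - ((days - sox17_peak_day) / sox17_peak_day)^2)))
  cxcr4 <- ifelse(days <= 2, cxcr4_plateau,
                  cxcr4_low + cxcr4_slope * (days - 3))
  cxcr4 <- pmax(0, pmin(1, cxcr4))

  if (noise_sd > 0) {
    set.seed(seed)
    growth_norm <- pmax(0, growth_norm + rnorm(6, 0, noise_sd))
    death_norm <- cummax(pmax(0, death_norm + rnorm(6, 0, noise_sd)))
    if (death_norm[5] > 0) death_norm <- death_norm / death_norm[5]
    if (growth_norm[5] > 0) growth_norm <- growth_norm / growth_norm[5]
    sox17 <- pmax(0, pmin(1, sox17 + rnorm(6, 0, noise_sd)))
    cxcr4 <- pmax(0, pmin(1, cxcr4 + rnorm(6, 0, noise_sd)))
  }

  structure(
    data.frame(day = days, growth_norm = growth_norm, death_norm = death_norm,
               frac_sox17 = sox17, frac_cxcr4 = cxcr4),
    condition = condition, noise_sd = noise_sd, seed = seed,
    provenance = "calibration",
    class = c("endoderm_data", "data.frame"))
}

#' Ground-truth dataset simulated from the model itself
#'
#' Runs [simulate_population()] at known parameters and converts the
#' aggregated mean trajectories into the dataset format used for fitting,
#' with growth and cumulative death normalised to their day-4 values. Used
#' for parameter-recovery and self-consistency tests: fitting data generated
#' by the model at `params` should recover trajectories matching `params`'s.
#'
#' @inheritParams simulate_population
#' @return An `"endoderm_data"` object with provenance `"ground-truth"` and
#'   the generating parameters attached as attribute `true_params`.
#' @export
generate_ground_truth <- function(params, mech, settings,
                                  seed = settings$seed) {
  ts <- simulate_population(params, mech, settings, seed = seed)
  s <- ts$summary
  i4 <- which(s$day == 4)
  if (!length(i4))
    stop("ground-truth generation needs an observation at day 4")
  growth_norm <- s$live_count / s$live_count[i4]
  if (s$cumulative_dead[i4] > 0) {
    death_norm <- s$cumulative_dead / s$cumulative_dead[i4]
  } else {
    warning("no deaths by day 4; death series left unnormalised")
    death_norm <- s$cumulative_dead
  }
  structure(
    data.frame(day = s$day, growth_norm = growth_norm,
               death_norm = death_norm, frac_sox17 = s$frac_sox17,
               frac_cxcr4 = s$frac_cxcr4),
    condition = NA_character_, noise_sd = 0, seed = seed,
    provenance = "ground-truth", true_params = params, mechanism = mech$id,
    class = c("endoderm_data", "data.frame"))
}

#' Fraction-of-maximum validation proxy curves
#'
#' Normalises the undifferentiated (hESC) and mesendoderm population fraction
#' trajectories each to its own maximum over days, producing the
#' percent-of-maximum curves against which the qPCR proxies (Oct4 for
#' undifferentiated cells, Brachyury for mesendoderm) are compared
#' qualitatively.
#'
#' @param trajectories A `"trajectory_set"` from [simulate_population()].
#' @return A data.frame with columns `day`, `undifferentiated`,
#'   `mesendoderm`, each series scaled so its maximum equals 1.
#' @export
validation_proxy <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  s <- trajectories$summary
  norm <- function(v, what) {
    m <- max(v, na.rm = TRUE)
    if (!is.finite(m) || m <= 0)
      stop("normalisation undefined: ", what, " series is all zero")
    v / m
  }
  data.frame(day = s$day,
             undifferentiated = norm(s$frac_hesc, "undifferentiated"),
             mesendoderm = norm(s$frac_mesendoderm, "mesendoderm"))
}

#' @export
print.endoderm_data <- function(x, ...) {
  cat(sprintf("Endoderm induction dataset (%s%s, noise sd %g)\n",
              attr(x, "provenance"),
              if (!is.na(attr(x, "condition")))
                paste0(", condition ", attr(x, "condition")) else "",
              attr(x, "noise_sd")))
  print(as.data.frame(lapply(x, signif, digits = 4)), row.names = FALSE)
  invisible(x)
}
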