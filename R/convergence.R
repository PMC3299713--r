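#' Two-dimensional convergence study
#'
#' Simulates the model over a grid of initial population sizes and replicate
#' run counts and records the day-5 CXCR4+ population fraction averaged over
#' runs (the convergence diagnostic), together with its run-to-run
#' dispersion. The converged operating point is the smallest grid point whose
#' mean differs from the value at the largest grid point by less than `tol`.
#'
#' @param params A [model_params()].
#' @param mech A [mechanism()].
#' @param n_initial_grid,n_runs_grid Strictly increasing grids. The defaults
#'   span the desk scale up to the full operating scale (9000 cells x 4000
#'   runs) and take substantial time at the upper end; pass smaller grids for
#'   exploratory work.
#' @param tol Convergence tolerance on the day-5 CXCR4+ mean, as a fraction
#'   (default 0.01, i.e. one percentage point).
#' @param seed Master seed.
#' @param horizon,observation_interval Passed to [sim_settings()].
#' @return An object of class `"convergence_surface"`: a data.frame with
#'   columns `n_initial`, `n_runs`, `mean_cxcr4`, `sd_cxcr4`, and attributes
#'   `converged` (row of the smallest converged grid point), `reference`
#'   (value at the largest grid point) and `tol`.
#' @export
convergence_study <- function(params, mech,
                              n_initial_grid = c(500, 1000, 3000, 9000),
                              n_runs_grid = c(100, 500, 2000, 4000),
                              tol = 0.01, seed = 1, horizon = 120,
                              observation_interval = 24) {
  stopifnot(all(diff(n_initial_grid) > 0), all(diff(n_runs_grid) > 0),
            tol > 0)
  grid <- expand.grid(n_initial = n_initial_grid, n_runs = n_runs_grid)
  res <- vapply(seq_len(nrow(grid)), function(i) {
    st <- sim_settings(n_initial = grid$n_initial[i], n_runs = grid$n_runs[i],
                       horizon = horizon,
                       observation_interval = observation_interval,
                       seed = seed)
    ts <- simulate_population(params, mech, st)
    r <- ts$runs[ts$runs$day == max(ts$runs$day), "frac_cxcr4"]
    c(mean(r, na.rm = TRUE),
      if (sum(!is.na(r)) > 1) sd(r, na.rm = TRUE) else 0)
  }, numeric(2))
  surf <- cbind(grid, mean_cxcr4 = res[1, ], sd_cxcr4 = res[2, ])
  ref <- surf$mean_cxcr4[which.max(surf$n_initial * surf$n_runs)]
  conv <- surf[abs(surf$mean_cxcr4 - ref) < tol, ]
  conv <- conv[order(conv$n_initial * conv$n_runs,
                     conv$n_initial, conv$n_runs), ]
  structure(surf, class = c("convergence_surface", "data.frame"),
            converged = if (nrow(conv)) conv[1, ] else NULL,
            reference = ref, tol = tol)
}

#' @export
print.convergence_surface <- function(x, ...) {
  cat("Convergence surface (day-5 CXCR4+ mean over runs):\n")
  y <- as.data.frame(x)
  y$mean_cxcr4 <- signif(y$mean_cxcr4, 4)
  y$sd_cxcr4 <- signif(y$sd_cxcr4, 3)
  print(y, row.names = FALSE)
  conv <- attr(x, "converged")
  if (!is.null(conv))
    cat(sprintf(
      "Converged point (within %.3g of largest grid point): %d cells x %d runs\n",
      attr(x, "tol"), conv$n_initial, conv$n_runs))
  invisible(x)
}
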