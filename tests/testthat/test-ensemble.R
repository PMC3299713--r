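test_that("parameter spaces validate bounds and sampling stays inside them", {
  expect_error(parameter_space(c(a = 1), c(b = 2)), "named identically")
  expect_error(parameter_space(c(a = 2), c(a = 1)), "strictly below")
  sp <- parameter_space(c(a = 0, b = 10), c(a = 1, b = 20))
  m <- sample_parameter_space(sp, 200, seed = 4)
  expect_equal(dim(m), c(200L, 2L))
  expect_true(all(m[, "a"] >= 0 & m[, "a"] <= 1))
  expect_true(all(m[, "b"] >= 10 & m[, "b"] <= 20))
  expect_identical(m, sample_parameter_space(sp, 200, seed = 4))
  expect_false(identical(m, sample_parameter_space(sp, 200, seed = 5)))
})

test_that("default spaces sample only parameters the mechanism reads", {
  sp_me <- default_parameter_space(mech_b())
  expect_true(all(c("a_0max2", "nprog_me", "nprog_de2", "nprog_meso2")
                  %in% sp_me$names))
  sp_direct <- default_parameter_space(mechanism(id = "ME-/CX-/U"))
  expect_false(any(c("a_0max2", "nprog_me") %in% sp_direct$names))
  expect_true(all(c("nprog_de", "nprog_meso") %in% sp_direct$names))
})

test_that("trajectory error is the mean squared marker residual", {
  d <- generate_calibration_data("A")
  expect_equal(trajectory_error(d, d), 0)
  shifted <- d
  shifted$frac_sox17 <- d$frac_sox17 + 0.1
  shifted$frac_cxcr4 <- d$frac_cxcr4 + 0.1
  expect_equal(trajectory_error(shifted, d), 0.01)
  # invariant to rescaling of live counts: only fractions enter
  fake <- data.frame(day = d$day, live_count = 1:6,
                     frac_sox17 = d$frac_sox17, frac_cxcr4 = d$frac_cxcr4)
  expect_equal(trajectory_error(fake, d), 0)
  misaligned <- data.frame(day = c(0, 2, 4), frac_sox17 = 0, frac_cxcr4 = 0)
  expect_error(trajectory_error(misaligned, d), "align")
})

test_that("acceptance mask follows the threshold definition", {
  d <- generate_calibration_data("A")
  st <- tiny_settings(n_initial = 100, n_runs = 3, seed = 1)
  suppressWarnings(
    fit <- fit_ensemble(d, mech_b(), st, n_samples = 25, threshold = 0.01,
                        seed = 3))
  expect_true(all(fit$errors[fit$accepted] <= 0.01))
  expect_true(all(fit$errors >= 0))
  expect_equal(fit$best_error, min(fit$errors))
  expect_equal(unname(fit$errors[fit$best_index]), fit$best_error)

  # infinite threshold accepts every simulable sample
  suppressWarnings(
    all_in <- fit_ensemble(d, mech_b(), st, n_samples = 25, threshold = Inf,
                           seed = 3))
  expect_equal(sum(all_in$accepted), sum(is.finite(all_in$errors)))
})

test_that("fit methods are mutually coherent", {
  d <- generate_calibration_data("A")
  st <- tiny_settings(n_initial = 100, n_runs = 3, seed = 1)
  suppressWarnings(
    fit <- fit_ensemble(d, mech_b(), st, n_samples = 20, threshold = 0.025,
                        seed = 8))
  cf <- coef(fit)
  expect_named(cf)
  expect_equal(unname(cf), unname(fit$samples[fit$best_index, ]))
  pr <- predict(fit)
  expect_true(all(c("frac_hesc", "frac_sox17", "frac_cxcr4") %in% names(pr)))
  # re-simulating the best fit at the fit seed reproduces the stored
  # trajectory (common random numbers)
  re <- simulate(fit)
  expect_equal(re$summary, fit$best_trajectory$summary)
  res <- residuals(fit)
  expect_equal(res$sox17,
               pr$frac_sox17[match(d$day, pr$day)] - d$frac_sox17)
  # the reported error is consistent with the residuals
  expect_equal(mean(res$sox17^2 + res$cxcr4^2) / 2, fit$best_error)
})

test_that("fitting model-generated data recovers the generating trajectories", {
  # data simulated at known parameters, fitted at small scale: the best-fit
  # marker trajectories must approach the generating ones
  truth <- model_params()
  gt <- generate_ground_truth(truth, mech_b(),
                              sim_settings(n_initial = 1000, n_runs = 30,
                                           seed = 77))
  st <- tiny_settings(n_initial = 250, n_runs = 8, seed = 1)
  suppressWarnings(
    fit <- fit_ensemble(gt, mech_b(), st, n_samples = 60, threshold = 0.025,
                        seed = 9))
  expect_lt(fit$best_error, 0.01)
})
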