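test_that("noise-free calibration curves satisfy the documented features", {
  for (cond in c("A", "B")) {
    d <- generate_calibration_data(cond)
    expect_equal(d$day, 0:5)
    # day-4 normalisation
    expect_equal(d$growth_norm[d$day == 4], 1)
    expect_equal(d$death_norm[d$day == 4], 1)
    # cumulative death linear and nondecreasing
    expect_true(all(diff(d$death_norm) >= 0))
    expect_equal(unique(round(diff(d$death_norm), 10)), 0.25)
    # Sox17: concave quadratic through zero, peak in the 19-23% band on
    # days 2-3
    expect_equal(d$frac_sox17[d$day == 0], 0)
    pk <- which.max(d$frac_sox17)
    expect_true(d$day[pk] %in% c(2, 3))
    expect_gte(max(d$frac_sox17), 0.19)
    expect_lte(max(d$frac_sox17), 0.23)
    # CXCR4: flat plateau to day 2, drop at the day-3 sample, then rise
    expect_equal(d$frac_cxcr4[d$day == 1], d$frac_cxcr4[d$day == 0])
    expect_equal(d$frac_cxcr4[d$day == 2], d$frac_cxcr4[d$day == 0])
    expect_lt(d$frac_cxcr4[d$day == 3], d$frac_cxcr4[d$day == 2])
    expect_gt(d$frac_cxcr4[d$day == 4], d$frac_cxcr4[d$day == 3])
    expect_gt(d$frac_cxcr4[d$day == 5], d$frac_cxcr4[d$day == 4])
    # fractions are valid
    expect_true(all(d$frac_sox17 >= 0 & d$frac_sox17 <= 1))
    expect_true(all(d$frac_cxcr4 >= 0 & d$frac_cxcr4 <= 1))
    # deterministic
    expect_identical(d, generate_calibration_data(cond))
  }
  # Condition B: growth concentrated before day 3, steeper CXCR4 rise
  a <- generate_calibration_data("A")
  b <- generate_calibration_data("B")
  expect_gt(b$growth_norm[b$day == 3] / b$growth_norm[b$day == 0], 1.5)
  expect_lt(a$growth_norm[a$day == 3], a$growth_norm[a$day == 0])
  expect_gt(diff(b$frac_cxcr4[b$day >= 4]), diff(a$frac_cxcr4[a$day >= 4]))
})

test_that("measurement noise respects the physical ranges", {
  d <- generate_calibration_data("A", noise_sd = 0.2, seed = 10)
  expect_true(all(d$frac_sox17 >= 0 & d$frac_sox17 <= 1))
  expect_true(all(d$frac_cxcr4 >= 0 & d$frac_cxcr4 <= 1))
  expect_true(all(diff(d$death_norm) >= 0))
  expect_true(all(d$growth_norm >= 0))
  expect_equal(d$death_norm[d$day == 4], 1)
  expect_identical(d, generate_calibration_data("A", noise_sd = 0.2,
                                                seed = 10))
  expect_false(identical(as.data.frame(d),
                         as.data.frame(generate_calibration_data("A"))))
})

test_that("ground-truth datasets pass the simulator's fractions through", {
  p <- model_params()
  st <- sim_settings(n_initial = 300, n_runs = 5, seed = 44)
  ts <- simulate_population(p, mech_b(), st)
  gt <- generate_ground_truth(p, mech_b(), st)
  expect_equal(gt$frac_sox17, ts$summary$frac_sox17)
  expect_equal(gt$frac_cxcr4, ts$summary$frac_cxcr4)
  expect_equal(gt$growth_norm[gt$day == 4], 1)
  expect_identical(attr(gt, "provenance"), "ground-truth")
  # self-consistency at matched seeds: zero error by construction
  expect_equal(trajectory_error(ts, gt), 0)
})

test_that("validation proxies normalise each series to its own maximum", {
  p <- model_params(nprog = c(me = 0, ve = 0, de = 0, meso = 0,
                              de2 = 0, meso2 = 0))
  ts <- simulate_population(p, mech_b(), tiny_settings(n_initial = 100))
  # constant all-hESC series normalises to ones; mesendoderm never appears
  expect_error(validation_proxy(ts), "mesendoderm")

  ts2 <- simulate_population(model_params(), mech_b(),
                             tiny_settings(n_initial = 400, n_runs = 4))
  vp <- validation_proxy(ts2)
  expect_equal(max(vp$undifferentiated), 1)
  expect_equal(max(vp$mesendoderm), 1)
  expect_equal(vp$undifferentiated[vp$day == 0], 1)  # unique max at day 0
})
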