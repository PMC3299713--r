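test_that("trajectories are a pure function of parameters and seed", {
  p <- model_params()
  m <- mech_b()
  st <- tiny_settings(n_initial = 200, n_runs = 3, seed = 11)
  a <- simulate_population(p, m, st)
  b <- simulate_population(p, m, st)
  expect_identical(a$runs, b$runs)
  expect_identical(a$summary, b$summary)
  c <- simulate_population(p, m, st, seed = 12)
  expect_false(identical(a$runs, c$runs))
})

test_that("a 120 h horizon with daily observation yields six snapshots", {
  ts <- simulate_population(model_params(), mech_b(),
                            tiny_settings(n_initial = 50, n_runs = 1))
  expect_equal(ts$summary$day, 0:5)
  expect_equal(nrow(ts$runs), 6)
})

test_that("model invariants hold across randomized parameters and mechanisms", {
  # conservation, regime/affinity consistency, competence latch and
  # sub-threshold propensities are checked inside the engine every snapshot
  set.seed(202)
  mechs <- enumerate_mechanisms()
  for (rep in 1:8) {
    p <- model_params(
      a_min = runif(1, 0.02, 0.3), d = 1 + runif(1, 0.005, 0.2),
      t_g1 = runif(1, 2, 20), l_max = runif(1, 80, 400),
      w_max = runif(1, 24, 150), aa = runif(1, 0, 3),
      a_0max2 = runif(1, 0.1, 1),
      nprog = c(me = runif(1, 0, 20), ve = runif(1, 0, 20),
                de = runif(1, 0, 20), meso = runif(1, 0, 20),
                de2 = runif(1, 0, 20), meso2 = runif(1, 0, 20)))
    m <- mechs[[sample.int(12, 1)]]
    ts <- simulate_population(p, m, tiny_settings(n_initial = 150, n_runs = 2,
                                                  seed = rep),
                              check_invariants = TRUE)
    r <- ts$runs
    expect_equal(r$live_count + r$cumulative_dead - r$divisions,
                 rep(150, nrow(r)))
    expect_true(all(diff(r$cumulative_dead[r$run == 1]) >= 0))
    expect_true(all(diff(r$cumulative_dead[r$run == 2]) >= 0))
    # phenotype fractions sum to one over live cells
    fr <- rowSums(r[r$live_count > 0, paste0("frac_", tolower(PHENOTYPES))])
    expect_equal(unname(fr), rep(1, length(fr)))
  }
})

test_that("committed lineages are absorbing at the population level", {
  # without death or new commitments a terminal count can never decrease;
  # here: commitments only add, deaths subtract, so count + cumulative
  # deaths of that lineage must be nondecreasing. We verify the weaker
  # observable consequence: with no death (huge lifespans) terminal counts
  # are nondecreasing day over day.
  p <- model_params(l_min = 1e5, l_max = 2e5)
  ts <- simulate_population(p, mech_b(),
                            tiny_settings(n_initial = 300, n_runs = 2,
                                          seed = 5),
                            check_invariants = TRUE)
  for (run in 1:2) {
    r <- ts$runs[ts$runs$run == run, ]
    for (ph in c("n_VISCERAL_ENDODERM", "n_DEFINITIVE_ENDODERM",
                 "n_MESODERM")) {
      expect_true(all(diff(r[[ph]]) >= 0))
    }
  }
})

test_that("zero propensity updates mean no commitment and no markers", {
  p <- model_params(nprog = c(me = 0, ve = 0, de = 0, meso = 0,
                              de2 = 0, meso2 = 0))
  ts <- simulate_population(p, mech_b(), tiny_settings(n_initial = 200))
  expect_true(all(ts$runs$frac_sox17 == 0))
  expect_true(all(ts$runs$frac_cxcr4 == 0))
  expect_true(all(ts$runs$n_HESC == ts$runs$live_count))
})

test_that("the A regime empties or fills according to the transfer scale", {
  # aa = 0: the A regime never gains cells
  p0 <- model_params(aa = 0)
  ts0 <- simulate_population(p0, mech_b(), tiny_settings(n_initial = 200))
  expect_true(all(ts0$runs$n_regime_a == 0))
  # large aa with no crowding: cells occupy A from the first day
  p1 <- model_params(aa = 1e6, n_scale = 1e9)
  ts1 <- simulate_population(p1, mech_b(), tiny_settings(n_initial = 200))
  expect_true(all(ts1$runs$n_regime_a[ts1$runs$day >= 1] > 0))
})

test_that("without death and with universal proliferation the population never shrinks", {
  p <- model_params(l_min = 1e5, l_max = 2e5)
  ts <- simulate_population(p, mechanism(id = "ME+/CX-/A"),
                            tiny_settings(n_initial = 200, n_runs = 2))
  for (run in 1:2)
    expect_true(all(diff(ts$runs$live_count[ts$runs$run == run]) >= 0))
})

test_that("single-run aggregation is the run itself with zero dispersion", {
  ts <- simulate_population(model_params(), mech_b(),
                            tiny_settings(n_initial = 100, n_runs = 1))
  expect_equal(ts$summary$live_count, ts$runs$live_count)
  expect_equal(ts$summary$sd_live_count, rep(0, 6))
})

test_that("dispersion of the aggregated day-5 CXCR4 mean shrinks with run count", {
  p <- model_params()
  m <- mech_b()
  mean_d5 <- function(n_runs, seed) {
    ts <- simulate_population(p, m, tiny_settings(n_initial = 60,
                                                  n_runs = n_runs,
                                                  seed = seed))
    ts$summary$frac_cxcr4[ts$summary$day == 5]
  }
  few <- vapply(1:10, function(s) mean_d5(4, 1000 + s), 0)
  many <- vapply(1:10, function(s) mean_d5(16, 2000 + s), 0)
  # Monte-Carlo SEM ~ 1/sqrt(n_runs): 4x the runs should roughly halve the
  # spread; allow a broad factor for the small number of replicates
  expect_lt(sd(many), sd(few))
})

test_that("the compiled engine matches the R reference loop in deterministic limits", {
  m <- mech_b()
  # (1) death only: a_min = 0 means no cell ever becomes competent, so the
  # only events are ageing and death at the assigned lifespans
  p1 <- endosim:::validate_model_params(modifyList(unclass(model_params()),
                                         list(a_min = 1e-12, aa = 0)))
  ts1 <- simulate_population(p1, m, tiny_settings(n_initial = 120, n_runs = 1,
                                                  seed = 21),
                             return_cells = TRUE)
  ref1 <- endosim:::ref_simulate(ts1$initial_cells, p1, m)
  expect_equal(ref1$live_count, ts1$runs$live_count)
  expect_equal(ref1$cumulative_dead, ts1$runs$cumulative_dead)

  # (2) division without death: immortal cells, immediate competence, and a
  # horizon shorter than one full daughter cycle so every division time is
  # determined by the initial cell table alone
  p2 <- model_params(a_min = 0.99, a_0max = 1, d = 1.5, aa = 0,
                     l_min = 1e5, l_max = 2e5, w_max = 1e6, t_cycle = 60,
                     t_g1 = 1e-9,
                     nprog = c(me = 0, ve = 0, de = 0, meso = 0,
                               de2 = 0, meso2 = 0))
  st2 <- tiny_settings(n_initial = 120, n_runs = 1, seed = 22, horizon = 48,
                       observation_interval = 24)
  ts2 <- simulate_population(p2, m, st2, return_cells = TRUE)
  ref2 <- endosim:::ref_simulate(ts2$initial_cells, p2, m, horizon = 48)
  expect_equal(ref2$live_count, ts2$runs$live_count)
  expect_equal(ref2$divisions, ts2$runs$divisions)
  expect_gt(ts2$runs$divisions[3], 0)  # the scenario does exercise division
})

test_that("extinct runs terminate with zero-filled observations and a warning", {
  # 2 h lifespans and no A-regime refuge (aa = 0): the population cannot
  # survive to the first daily observation
  p <- model_params(l_min = 1, l_max = 2, aa = 0)
  expect_warning(
    ts <- simulate_population(p, mech_b(), tiny_settings(n_initial = 30)),
    "extinct")
  r <- ts$runs
  expect_true(all(r$live_count[r$day >= 1] == 0))
  expect_equal(r$cumulative_dead[r$day == 5], 30 + r$divisions[r$day == 5])
  expect_true(all(ts$extinct))
})
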