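# Contracts of the per-cell operations (R reference implementation).

test_that("initial populations are undifferentiated, cycling, zero-propensity", {
  p <- model_params()
  pop <- init_population(sim_settings(n_initial = 500, seed = 3), p)
  expect_equal(nrow(pop), 500)
  expect_true(all(pop$phenotype == "HESC"))
  expect_true(all(pop$regime == "OMEGA"))
  expect_true(all(pop$age == 0))
  expect_true(all(pop$a_value > 0 & pop$a_value <= p$a_0max))
  expect_true(all(pop$life_span >= p$l_min & pop$life_span <= p$l_max))
  expect_true(all(pop$cycle_position >= 0 & pop$cycle_position < p$t_cycle))
  expect_true(all(pop$prop_1 == 0 & pop$prop_2 == 0 & pop$prop_3 == 0))

  again <- init_population(sim_settings(n_initial = 500, seed = 3), p)
  expect_identical(pop, again)
  other <- init_population(sim_settings(n_initial = 500, seed = 4), p)
  expect_false(identical(sort(pop$a_value), sort(other$a_value)))
})

test_that("affinity is frozen in A, decays geometrically in Omega", {
  p <- model_params(d = 1.1)
  a_cell <- one_cell(regime = "A", a_value = 0.5)
  expect_equal(update_affinity(a_cell, p)$a_value, 0.5)

  p2 <- model_params(d = 2)
  om <- one_cell(a_value = 1)
  for (k in 1:3) om <- update_affinity(om, p2)
  expect_equal(om$a_value, 1 / 2^3)  # closed form a / d^k
})

test_that("the proliferation-competence latch is permanent", {
  p <- model_params(a_min = 0.4, d = 2)
  cell <- one_cell(a_value = 0.5)
  cell <- update_affinity(cell, p)  # 0.25 < a_min: latches
  expect_true(cell$proliferation_competent)
  # even if the threshold later drops below the current affinity
  p_low <- model_params(a_min = 0.01, d = 1.01)
  cell2 <- update_affinity(cell, p_low)
  expect_true(cell2$proliferation_competent)
})

test_that("transfer to A is impossible below a_min or outside G1", {
  p <- model_params(aa = 100, n_scale = 1e9)
  below <- one_cell(a_value = p$a_min / 2, cycle_position = 0)
  post_g1 <- one_cell(a_value = 0.9, cycle_position = p$t_g1 + 1)
  set.seed(1)
  for (i in 1:50) {
    expect_identical(transfer_step(below, 10, 10, p)$regime, "OMEGA")
    expect_identical(transfer_step(post_g1, 10, 10, p)$regime, "OMEGA")
  }
})

test_that("A -> Omega transfer is certain at a = a_min with no crowding", {
  p <- model_params()
  cell <- one_cell(regime = "A", a_value = p$a_min)
  expect_identical(transfer_step(cell, 0, 1, p)$regime, "OMEGA")
})

test_that("propensities converge to their mean on Omega -> A transfer", {
  p <- model_params(aa = 1e6, n_scale = 1e12)  # transfer certain in G1
  cell <- one_cell(a_value = p$a_0max, cycle_position = 0,
                   prop_1 = 0.2, prop_2 = 0.4)
  out <- transfer_step(cell, 1, 0, p, mechanism())
  expect_identical(out$regime, "A")
  expect_equal(out$prop_1, 0.3)
  expect_equal(out$prop_2, 0.3)
})

test_that("propensity updates are G1- and Omega-gated and never decrease", {
  p <- model_params()
  m <- mechanism()
  in_a <- one_cell(regime = "A", prop_1 = 0.1)
  expect_equal(propensity_update(in_a, p, m)$prop_1, 0.1)
  post_g1 <- one_cell(cycle_position = p$t_g1, prop_1 = 0.1)
  expect_equal(propensity_update(post_g1, p, m)$prop_1, 0.1)

  committed <- one_cell(phenotype = "MESODERM")
  expect_error(propensity_update(committed, p, m), "committed")

  # zero update magnitudes freeze the propensities entirely
  p0 <- model_params(nprog = c(me = 0, ve = 0, de = 0, meso = 0,
                               de2 = 0, meso2 = 0))
  cell <- one_cell()
  set.seed(1)
  for (i in 1:20) cell <- propensity_update(cell, p0, m)
  expect_equal(unlist(cell[c("prop_1", "prop_2", "prop_3")]),
               c(prop_1 = 0, prop_2 = 0, prop_3 = 0))
})

test_that("the leading lineage is selected preferentially", {
  p <- model_params()
  m <- mechanism()
  cell <- one_cell(prop_1 = 0.9 * p$x_com, prop_2 = 0)
  set.seed(7)
  wins <- replicate(400, {
    out <- propensity_update(cell, p, m)
    out$prop_1 > cell$prop_1
  })
  # selection weights (0.9 + 0.01) vs 0.01: lineage 1 nearly always
  expect_gt(mean(wins), 0.5)
})

test_that("mesendoderm commitment re-initialises stage-2 state", {
  p <- model_params()
  m <- mechanism()
  cell <- one_cell(prop_1 = p$x_com, prop_2 = 0.3,
                   proliferation_competent = TRUE, proliferation_clock = 5)
  set.seed(2)
  out <- commit_cell(cell, "MESENDODERM", p, m)
  expect_identical(out$phenotype, "MESENDODERM")
  expect_identical(out$stage, 2L)
  expect_true(out$a_value > 0 && out$a_value <= p$a_0max2)
  expect_false(out$proliferation_competent)
  expect_equal(out$prop_1 + out$prop_2 + out$prop_3, 0)

  expect_error(commit_cell(one_cell(prop_1 = 0.5), "MESENDODERM", p, m),
               "below threshold")
})

test_that("terminal commitment is absorbing", {
  p <- model_params()
  m <- mechanism()
  cell <- one_cell(phenotype = "MESENDODERM", stage = 2L, prop_2 = p$x_com2)
  out <- commit_cell(cell, "MESODERM", p, m)
  expect_identical(out$phenotype, "MESODERM")
  expect_error(propensity_update(out, p, m), "committed")
})

test_that("A-regime cells neither age, die nor divide", {
  p <- model_params()
  cell <- one_cell(regime = "A", age = 999, life_span = 10,
                   proliferation_competent = TRUE,
                   cycle_position = p$t_cycle - 0.5)
  res <- death_and_proliferation_step(cell, p, mechanism())
  expect_equal(res$n_died, 0)
  expect_equal(res$n_divided, 0)
  expect_equal(res$cells$age, 999)
  expect_equal(res$cells$cycle_position, p$t_cycle - 0.5)
})

test_that("death and division follow lifespan, competence and scope", {
  p <- model_params()
  m <- mechanism(id = "ME+/CX-/EU")
  dying <- one_cell(age = 100, life_span = 100.5)
  res <- death_and_proliferation_step(dying, p, m)
  expect_equal(res$n_died, 1)
  expect_equal(nrow(res$cells), 0)

  # not competent: cycle wrap without division
  idle <- one_cell(cycle_position = p$t_cycle - 0.5)
  res <- death_and_proliferation_step(idle, p, m)
  expect_equal(res$n_divided, 0)

  # competent, in window, allowed phenotype: division with inherited state
  set.seed(9)
  mother <- one_cell(cycle_position = p$t_cycle - 0.5,
                     proliferation_competent = TRUE, a_value = 0.01,
                     phenotype = "DEFINITIVE_ENDODERM", prop_1 = 0.2)
  res <- death_and_proliferation_step(mother, p, m)
  expect_equal(res$n_divided, 1)
  expect_equal(nrow(res$cells), 2)
  d <- res$cells[2, ]
  expect_equal(d$age, 0)
  expect_equal(d$cycle_position, 0)
  expect_identical(d$phenotype, "DEFINITIVE_ENDODERM")
  expect_equal(d$a_value, 0.01)
  expect_equal(d$prop_1, 0.2)

  # mesoderm may not divide under the endoderm-and-uncommitted scope
  meso <- one_cell(cycle_position = p$t_cycle - 0.5,
                   proliferation_competent = TRUE, phenotype = "MESODERM")
  expect_equal(death_and_proliferation_step(meso, p, m)$n_divided, 0)
  expect_equal(death_and_proliferation_step(
    meso, p, mechanism(id = "ME+/CX-/A"))$n_divided, 1)

  # senescent: past the proliferation window
  old <- one_cell(cycle_position = p$t_cycle - 0.5,
                  proliferation_competent = TRUE,
                  proliferation_clock = 50, proliferation_window = 40)
  expect_equal(death_and_proliferation_step(old, p, m)$n_divided, 0)
})
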