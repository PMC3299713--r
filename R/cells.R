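# Reference (pure R) implementation of the per-cell rules.
#
# These functions operate on a population data.frame (one row per cell) and
# implement exactly the same update rules as the compiled engine behind
# simulate_population(). They are exported both as executable documentation of
# the model's rules and as an independent oracle: in deterministic limits the
# trajectories of the R reference loop and the C++ engine must agree exactly.

CELL_COLS <- c("regime", "a_value", "age", "life_span", "cycle_position",
               "proliferation_competent", "proliferation_clock",
               "proliferation_window", "phenotype", "stage",
               "prop_1", "prop_2", "prop_3")

#' Lineage slots reachable from a phenotype
#'
#' Stage-1 cells (hESC) can commit to mesendoderm or visceral endoderm when
#' the mechanism includes the mesendoderm intermediate, and directly to
#' definitive endoderm, visceral endoderm or mesoderm when it does not.
#' Stage-2 cells (mesendoderm) commit to definitive endoderm or mesoderm.
#'
#' @param stage 1 or 2.
#' @param mech A [mechanism()].
#' @return Character vector of phenotype names, one per propensity slot.
#' @export
lineage_slots <- function(stage, mech) {
  stopifnot(inherits(mech, "mechanism"), stage %in% c(1, 2))
  if (stage == 2) {
    if (!mech$include_mesendoderm)
      stop("stage 2 does not exist in mechanisms without mesendoderm")
    return(c("DEFINITIVE_ENDODERM", "MESODERM"))
  }
  if (mech$include_mesendoderm) c("MESENDODERM", "VISCERAL_ENDODERM")
  else c("DEFINITIVE_ENDODERM", "VISCERAL_ENDODERM", "MESODERM")
}

# nprog factors in slot order for a stage
nprog_slots <- function(params, stage, mech) {
  np <- params$nprog
  if (stage == 2) return(unname(np[c("de2", "meso2")]))
  if (mech$include_mesendoderm) unname(np[c("me", "ve")])
  else unname(np[c("de", "ve", "meso")])
}

#' Initialise a population of cells
#'
#' Creates `n_initial` undifferentiated (hESC, stage 1) cells, all in the
#' active Omega regime, age 0, with zero lineage propensities. Affinity is
#' drawn uniformly on `(0, a_0max]`, lifespan uniformly on `[l_min, l_max]`,
#' the proliferation window uniformly on `(0, w_max]` and the cell-cycle
#' position uniformly on `[0, t_cycle)`. Uses R's RNG, seeded from
#' `settings$seed`.
#'
#' @param settings A [sim_settings()].
#' @param params A [model_params()].
#' @return A population data.frame, one row per cell.
#' @examples
#' pop <- init_population(sim_settings(n_initial = 5, seed = 1), model_params())
#' nrow(pop)
#' @export
init_population <- function(settings, params) {
  stopifnot(inherits(settings, "sim_settings"), inherits(params, "model_params"))
  n <- settings$n_initial
  set.seed(settings$seed)
  data.frame(
    regime = rep("OMEGA", n),
    a_value = params$a_0max * (1 - runif(n)),
    age = 0,
    life_span = runif(n, params$l_min, params$l_max),
    cycle_position = runif(n, 0, params$t_cycle),
    proliferation_competent = FALSE,
    proliferation_clock = 0,
    proliferation_window = params$w_max * (1 - runif(n)),
    phenotype = "HESC",
    stage = 1L,
    prop_1 = 0, prop_2 = 0, prop_3 = 0,
    stringsAsFactors = FALSE
  )
}

#' One affinity-decay step
#'
#' In the Omega regime the affinity decays geometrically, `a <- a / d`; in the
#' A regime it is unaltered. A cell whose affinity first falls below `a_min`
#' permanently becomes proliferation-competent (and can never re-enter A).
#'
#' @param cells Population data.frame.
#' @param params A [model_params()].
#' @return Updated population data.frame.
#' @export
update_affinity <- function(cells, params) {
  om <- cells$regime == "OMEGA"
  cells$a_value[om] <- cells$a_value[om] / params$d
  newly <- om & !cells$proliferation_competent & cells$a_value < params$a_min
  cells$proliferation_competent[newly] <- TRUE
  cells$proliferation_clock[newly] <- 0
  cells
}

#' One regime-transfer step
#'
#' Omega -> A transfer can occur only during G1 (`cycle_position < t_g1`) and
#' only while `a >= a_min`, with probability
#' `min(1, aa * (a / a_0max) * f(n_a))` where `f(N) = 1 / (1 + N / n_scale)`
#' is the crowding of the destination regime (stage-2 cells are normalised by
#' `a_0max2`, the bound their affinity was redrawn from). A -> Omega transfer
#' occurs with probability `min(1, (a_min / a) * f(n_omega))`. On an
#' Omega -> A transfer the uncommitted lineage propensities converge to their
#' arithmetic mean.
#'
#' @param cells Population data.frame (affinity already updated this step).
#' @param n_omega,n_a Live totals per regime, frozen at the start of the step.
#' @param params A [model_params()].
#' @param mech A [mechanism()] (determines how many propensity slots are
#'   active when averaging).
#' @return Updated population data.frame.
#' @export
transfer_step <- function(cells, n_omega, n_a, params, mech = mechanism()) {
  f_a <- 1 / (1 + n_a / params$n_scale)
  f_omega <- 1 / (1 + n_omega / params$n_scale)
  n <- nrow(cells)
  if (n == 0) return(cells)
  u <- runif(n)
  in_a <- cells$regime == "A"
  q <- pmin(1, (params$a_min / cells$a_value) * f_omega)
  back <- in_a & u < q
  cells$regime[back] <- "OMEGA"

  norm <- ifelse(cells$stage == 2, params$a_0max2, params$a_0max)
  p <- pmin(1, params$aa * (cells$a_value / norm) * f_a)
  go <- !in_a & cells$cycle_position < params$t_g1 &
    cells$a_value >= params$a_min & u < p
  if (any(go)) {
    cells$regime[go] <- "A"
    for (i in which(go)) {
      if (!cells$phenotype[i] %in% c("HESC", "MESENDODERM")) next
      nl <- length(lineage_slots(cells$stage[i], mech))
      pr <- unlist(cells[i, c("prop_1", "prop_2", "prop_3")])[seq_len(nl)]
      cells[i, c("prop_1", "prop_2", "prop_3")[seq_len(nl)]] <- mean(pr)
    }
  }
  cells
}

#' One lineage-propensity update step
#'
#' Only cells in the Omega regime and in G1 update propensities; for each such
#' cell exactly one reachable lineage is selected with probability
#' proportional to `propensity + eps` (exploration constant
#' `eps = 0.01 * x_com` of the stage) and incremented by
#' `0.01 * x_com * nprog_i`. Propensities never decrease in Omega. Calling
#' this on committed (terminal-phenotype) cells is a contract violation.
#'
#' @param cells Population data.frame; all rows must be uncommitted.
#' @param params A [model_params()].
#' @param mech A [mechanism()].
#' @return Updated population data.frame.
#' @export
propensity_update <- function(cells, params, mech) {
  if (any(!cells$phenotype %in% c("HESC", "MESENDODERM")))
    stop("propensity_update called on a committed cell")
  for (i in seq_len(nrow(cells))) {
    if (cells$regime[i] != "OMEGA" || cells$cycle_position[i] >= params$t_g1)
      next
    st <- cells$stage[i]
    slots <- lineage_slots(st, mech)
    nl <- length(slots)
    xc <- if (st == 1) params$x_com else params$x_com2
    eps <- 0.01 * xc
    delta <- 0.01 * xc
    npr <- nprog_slots(params, st, mech)
    pr <- as.numeric(cells[i, c("prop_1", "prop_2", "prop_3")[seq_len(nl)]])
    j <- sample.int(nl, 1L, prob = pr + eps)
    cells[i, c("prop_1", "prop_2", "prop_3")[j]] <- pr[j] + delta * npr[j]
  }
  cells
}

#' Commit cells to a lineage
#'
#' Commits each row of `cells` to `lineage`, requiring its propensity to have
#' reached the stage threshold (`x_com` / `x_com2`). Commitment to mesendoderm
#' enters stage 2: the affinity is redrawn uniformly on `(0, a_0max2]`,
#' proliferation competence is reset, and the propensities restart at zero
#' over the stage-2 lineages. Terminal lineages fix the phenotype and freeze
#' the propensity map permanently.
#'
#' @param cells Population data.frame rows to commit.
#' @param lineage Phenotype name the cells commit to.
#' @param params A [model_params()].
#' @param mech A [mechanism()].
#' @return Updated rows.
#' @export
commit_cell <- function(cells, lineage, params, mech = mechanism()) {
  lineage <- match.arg(lineage, PHENOTYPES[-1])
  n <- nrow(cells)
  if (n == 0) return(cells)
  st <- cells$stage
  slots <- lapply(st, lineage_slots, mech = mech)
  thr <- ifelse(st == 1, params$x_com, params$x_com2)
  for (i in seq_len(n)) {
    j <- match(lineage, slots[[i]])
    if (is.na(j))
      stop("lineage ", lineage, " is not reachable from phenotype ",
           cells$phenotype[i], " at stage ", st[i])
    if (cells[i, c("prop_1", "prop_2", "prop_3")[j]] < thr[i])
      stop("commitment below threshold: propensity for ", lineage,
           " has not reached the stage-", st[i], " commitment threshold")
  }
  if (lineage == "MESENDODERM") {
    cells$phenotype <- "MESENDODERM"
    cells$stage <- 2L
    cells$a_value <- params$a_0max2 * (1 - runif(n))
    cells$proliferation_competent <- FALSE
    cells$proliferation_clock <- 0
    cells$prop_1 <- 0
    cells$prop_2 <- 0
    cells$prop_3 <- 0
  } else {
    cells$phenotype <- lineage
  }
  cells
}

#' One ageing / death / proliferation step
#'
#' Cells in the A regime are fully quiescent: age, cycle position and
#' proliferation clock are frozen and they can neither die nor divide. In the
#' Omega regime a cell ages by `dt` and dies when its age exceeds its assigned
#' lifespan. Division occurs when the cell-cycle position wraps past
#' `t_cycle`, provided the cell is proliferation-competent (affinity crossed
#' below `a_min`), still within its proliferation window (not senescent), and
#' its phenotype may proliferate under the mechanism. A daughter inherits
#' phenotype, stage, propensities and affinity; her age, cycle position and
#' clock restart at zero and her lifespan and window are freshly drawn.
#'
#' @param cells Population data.frame.
#' @param params A [model_params()].
#' @param mech A [mechanism()].
#' @return A list: `cells` (survivors plus daughters), `n_died`, `n_divided`.
#' @export
death_and_proliferation_step <- function(cells, params, mech = mechanism()) {
  om <- cells$regime == "OMEGA"
  cells$age[om] <- cells$age[om] + params$dt
  dead <- om & cells$age > cells$life_span
  n_died <- sum(dead)
  cells <- cells[!dead, , drop = FALSE]
  om <- cells$regime == "OMEGA"
  cells$cycle_position[om] <- cells$cycle_position[om] + params$dt
  tick <- om & cells$proliferation_competent
  cells$proliferation_clock[tick] <- cells$proliferation_clock[tick] + params$dt
  wrap <- om & cells$cycle_position >= params$t_cycle
  cells$cycle_position[wrap] <- cells$cycle_position[wrap] - params$t_cycle
  divide <- wrap & cells$proliferation_competent &
    cells$proliferation_clock <= cells$proliferation_window &
    cells$phenotype %in% PHENOTYPES[proliferation_allowed(PHENOTYPES, mech)]
  n_div <- sum(divide)
  if (n_div > 0) {
    daughters <- cells[divide, , drop = FALSE]
    daughters$age <- 0
    daughters$cycle_position <- 0
    daughters$proliferation_clock <- 0
    daughters$life_span <- runif(n_div, params$l_min, params$l_max)
    daughters$proliferation_window <- params$w_max * (1 - runif(n_div))
    cells <- rbind(cells, daughters)
  }
  rownames(cells) <- NULL
  list(cells = cells, n_died = n_died, n_divided = n_div)
}

# One full simulation step of the R reference loop, replicating the engine's
# event order: regime counts frozen at step start; A cells may return to
# Omega (and are then frozen for the rest of the step); Omega cells decay,
# may transfer to A (frozen thereafter), update propensities / commit in G1,
# then age, die and divide.
ref_step <- function(cells, params, mech) {
  was_omega <- cells$regime == "OMEGA"
  n_omega <- sum(was_omega)
  n_a <- nrow(cells) - n_omega
  cells <- update_affinity(cells, params)
  cells <- transfer_step(cells, n_omega, n_a, params, mech)
  active <- was_omega & cells$regime == "OMEGA"
  elig <- active & cells$cycle_position < params$t_g1 &
    cells$phenotype %in% c("HESC", "MESENDODERM")
  if (any(elig)) {
    upd <- propensity_update(cells[elig, , drop = FALSE], params, mech)
    # commitment check: a slot that reached its stage threshold commits
    for (i in seq_len(nrow(upd))) {
      st <- upd$stage[i]
      slots <- lineage_slots(st, mech)
      thr <- if (st == 1) params$x_com else params$x_com2
      pr <- as.numeric(upd[i, c("prop_1", "prop_2", "prop_3")[seq_along(slots)]])
      j <- which(pr >= thr)
      if (length(j))
        upd[i, ] <- commit_cell(upd[i, , drop = FALSE], slots[j[1]], params, mech)
    }
    cells[elig, ] <- upd
  }
  idle <- !(was_omega & cells$regime == "OMEGA")
  frozen <- cells[idle, , drop = FALSE]
  res <- death_and_proliferation_step(cells[!idle, , drop = FALSE], params, mech)
  list(cells = rbind(frozen, res$cells), n_died = res$n_died,
       n_divided = res$n_divided)
}

# R reference simulator (slow; used for small-population oracle tests).
# Returns a data.frame of daily observables like simulate_run().
ref_simulate <- function(cells, params, mech, horizon = 120,
                         observation_interval = 24) {
  n_steps <- round(horizon / params$dt)
  obs_every <- round(observation_interval / params$dt)
  n_init <- nrow(cells)
  snap <- function(day, dead, div) {
    cnt <- vapply(PHENOTYPES, function(ph) sum(cells$phenotype == ph), 0)
    data.frame(day = day, live_count = nrow(cells), cumulative_dead = dead,
               divisions = div, t(cnt))
  }
  dead <- 0; div <- 0
  out <- snap(0, dead, div)
  for (step in seq_len(n_steps)) {
    res <- ref_step(cells, params, mech)
    cells <- res$cells
    dead <- dead + res$n_died
    div <- div + res$n_divided
    if (step %% obs_every == 0)
      out <- rbind(out, snap(step * params$dt / 24, dead, div))
    if (nrow(cells) == 0) break
  }
  stopifnot(out$live_count + out$cumulative_dead - out$divisions == n_init)
  rownames(out) <- NULL
  out
}

# Convert the engine's cell matrix to the reference data.frame format.
cells_from_engine <- function(m) {
  data.frame(
    regime = ifelse(m[, "regime"] == 1, "A", "OMEGA"),
    a_value = m[, "a_value"],
    age = m[, "age"],
    life_span = m[, "life_span"],
    cycle_position = m[, "cycle_position"],
    proliferation_competent = m[, "proliferation_competent"] == 1,
    proliferation_clock = m[, "proliferation_clock"],
    proliferation_window = m[, "proliferation_window"],
    phenotype = PHENOTYPES[m[, "phenotype"] + 1],
    stage = as.integer(m[, "stage"]),
    prop_1 = m[, "prop1"], prop_2 = m[, "prop2"], prop_3 = m[, "prop3"],
    stringsAsFactors = FALSE
  )
}
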