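mini_state <- function(bio = 0.001, env = c(no3 = 0.05), t = 0) {
  dfba_state(t, c(protein = bio), env)
}

test_that("interval objectives follow the target-difference rules", {
  tg <- make_batch_timeseries(seed = 1)
  s <- dfba_state(0, c(protein = 0.004, chryso = 0.002), tg$environment_mM)
  obj <- interval_objective(s, tg, is_dark = FALSE)
  expect_identical(obj$mode, "biomass")
  expect_equal(sum(obj$fractions), 1)

  ## equal positive differences give equal fractions
  s2 <- dfba_state(0, c(protein = 0.001, chryso = 0.001), tg$environment_mM)
  tg2 <- tg
  pg <- 2 / (stats::approx(tg$days, tg$cells_per_L, 3 / 24, rule = 2)$y *
               1e-12)
  tg2$targets <- data.frame(day = c(1, 1),
                            component = c("protein", "chryso"),
                            pg_cell = c(pg, pg), stringsAsFactors = FALSE)
  tg2$fold_change <- numeric(0)
  obj2 <- interval_objective(s2, tg2, is_dark = FALSE)
  expect_equal(unname(obj2$fractions), c(0.5, 0.5))

  ## dark intervals drop the dark-excluded components even when growing
  obj_dark <- interval_objective(s, tg, is_dark = TRUE)
  expect_false(any(tg$dark_excluded %in% names(obj_dark$fractions)))

  ## everything above target: switch to maintenance
  s3 <- dfba_state(9.9 * 24, stats::setNames(
    rep(1, length(unique(tg$targets$component))),
    unique(tg$targets$component)), tg$environment_mM)
  obj3 <- interval_objective(s3, tg, is_dark = FALSE)
  expect_identical(obj3$mode, "ATPM")

  ## past the last target day the simulation ends cleanly
  s4 <- dfba_state(10.5 * 24, c(protein = 1), tg$environment_mM)
  expect_error(interval_objective(s4, tg, FALSE), "no future target")
})

test_that("uptake bounds take the gentler of kinetics and availability", {
  kin <- data.frame(metabolite = "no3", Vmax = 0.2, Km = 0.05)
  ## MM limb binds: 0.2*0.05/0.1 = 0.1 vs availability 16.67
  st <- mini_state(bio = 0.001, env = c(no3 = 0.05))
  b <- uptake_bounds(st, kin, dt = 3)
  expect_equal(unname(b[["EX_no3_e"]]), -0.1)
  ## exhausted pool gives a zero bound
  st0 <- mini_state(env = c(no3 = 0))
  expect_identical(unname(uptake_bounds(st0, kin, 3)[["EX_no3_e"]]), 0)
  ## availability limb binds with a large standing stock of biomass
  stb <- mini_state(bio = 10, env = c(no3 = 0.05))
  expect_equal(unname(uptake_bounds(stb, kin, 3)[["EX_no3_e"]]),
               -0.05 / (10 * 3))
  ## water and protons bypass the pool limit (buffered reservoir)
  sth <- mini_state(env = c(h = 1e-4, h2o = 1))
  bh <- uptake_bounds(sth, default_uptake_kinetics(), 3)
  expect_equal(unname(bh[["EX_h_e"]]), -1000)
})

test_that("remobilization bounds convert surplus mass to sink allowances", {
  st <- dfba_state(0, c(protein = 2), c(no3 = 1))
  fml <- c(protein = "C5H7NO3S0.02", rna = "C10H12N5O7P",
           chla = "C55H72MgN4O5")
  delta <- c(protein = -0.5, rna = 0.2, chla = -0.001)
  rb <- remobilization_bounds(st, delta, fml, dt = 3)
  expect_equal(unname(rb[["SK_protein_c"]]),
               -0.5 * 1000 / molar_mass(fml[["protein"]]) / (2 * 3))
  expect_false("SK_rna_c" %in% names(rb))        # rising pools are not sinks
  ## chlorophyll is force-degraded at the rate its pool declines
  expect_equal(unname(rb[["DM_chla_h"]]), -unname(rb[["SK_chla_h"]]))
  expect_gt(rb[["DM_chla_h"]], 0)
  expect_error(remobilization_bounds(st, c(protein = -1), c(rna = "C"), 3),
               "protein")
})

test_that("remobilized protein supports growth with nitrogen exchange closed", {
  m <- cached_toy_model()
  m <- set_bounds(m, "EX_no3_e", 0, 0)
  m <- set_bounds(m, "EX_nh4_e", 0, 1000)
  expect_lt(solve_fba(m)$objective_value, 1e-8)
  m2 <- set_bounds(m, "SK_protein_c", -1, 0)
  s <- solve_fba(m2)
  expect_gt(s$objective_value, 1e-4)
})

test_that("photosynthetic-quotient windows behave as electron accounting says", {
  ## carbohydrate-only biomass: the window degenerates to {1} * scale
  pq <- pq_bounds("C6H12O6", pq_scale = 1)
  expect_equal(unname(pq$window), c(1, 1))
  pq105 <- pq_bounds("C6H12O6", pq_scale = 1.05)
  expect_equal(unname(pq105$window), c(1.05, 1.05))
  ## nitrogen makes nitrate costlier than ammonium, never the reverse
  pqn <- pq_bounds("C5H8NO3", pq_scale = 1)
  expect_lte(pqn$pq_nh4, pqn$pq_no3)
  expect_warning(pq_bounds("CH2O", pq_scale = 1.2), "0.9-1.1")
})

test_that("the state update follows the exponential growth equations", {
  st <- dfba_state(0, c(protein = 0.01), c(no3 = 0.02, glyclt = 0))
  fl <- stats::setNames(c(0.1, -0.05, 0.02),
                        c("DM_biomass_c", "EX_no3_e", "EX_glyclt_e"))
  sol <- structure(list(status = "optimal", fluxes = fl), class = "flux_solution")
  st2 <- advance_state(st, sol, dt = 3, fractions = c(protein = 1),
                       component_formulas = toy_component_formulas(),
                       config = dfba_config(gas_mM = numeric(0)))
  expect_equal(st2$bio / st$bio, exp(0.1 * 3), tolerance = 1e-12)
  gf <- 0.01 * (exp(0.3) - 1) / 0.1
  expect_equal(st2$environment[["no3"]], 0.02 - 0.05 * gf, tolerance = 1e-12)
  expect_equal(st2$environment[["glyclt"]], 0.02 * gf, tolerance = 1e-12)

  ## mu -> 0 limit equals the explicit Euler update
  fl0 <- stats::setNames(c(1e-9, -0.05), c("DM_biomass_c", "EX_no3_e"))
  sol0 <- structure(list(status = "optimal", fluxes = fl0),
                    class = "flux_solution")
  st3 <- advance_state(st, sol0, 3, c(protein = 1),
                       toy_component_formulas(),
                       dfba_config(gas_mM = numeric(0)))
  expect_equal(st3$environment[["no3"]], 0.02 - 0.05 * 0.01 * 3,
               tolerance = 1e-6)
  ## zero flux leaves a pool untouched
  expect_equal(st3$environment[["glyclt"]], 0)
  ## negative growth flux is an error
  flneg <- stats::setNames(-0.1, "DM_biomass_c")
  expect_error(advance_state(st, structure(list(status = "optimal",
                                                fluxes = flneg),
                                           class = "flux_solution"),
                             3, numeric(0), toy_component_formulas(),
                             dfba_config(gas_mM = numeric(0))),
               "negative growth")
})

test_that("gases re-equilibrate and clamped mass is logged", {
  st <- dfba_state(0, c(protein = 0.01),
                   c(no3 = 1e-6, co2 = 0.0133, hco3 = 1.78, o2 = 0.21))
  fl <- stats::setNames(c(0.1, -0.5, -2), c("DM_biomass_c", "EX_co2_e",
                                            "EX_no3_e"))
  sol <- structure(list(status = "optimal", fluxes = fl),
                   class = "flux_solution")
  st2 <- advance_state(st, sol, 3, c(protein = 1), toy_component_formulas())
  expect_equal(st2$environment[["co2"]], 0.0133)  # reset to equilibrium
  expect_equal(st2$environment[["no3"]], 0)       # clamped
  led <- attr(st2, "ledger")
  expect_gt(led$gas_reset[["co2"]], 0)
  expect_true("no3" %in% names(led$clamped))
})

test_that("the reference batch run reproduces the starvation phenomenology", {
  tr <- cached_batch_run()
  t <- vapply(tr$states, `[[`, 0, "t")
  bio <- vapply(tr$states, `[[`, 0, "bio")
  no3 <- vapply(tr$states, function(s) s$environment[["no3"]], 0)

  ## nitrate depletion precedes growth cessation
  dep <- which(no3 < 5e-4)[1]
  expect_false(is.na(dep))
  last_growth <- max(which(tr$mu > 1e-4))
  expect_lt(dep, last_growth)
  ## growth continues transiently on remobilized N after depletion
  expect_gt(bio[length(bio)], bio[dep])
  ## nitrate mass never exceeds its initial value (no sources)
  expect_true(all(no3 <= no3[1] + 1e-9))
  ## infeasible intervals, if any, are recorded rather than silent
  expect_identical(length(tr$modes), length(tr$solutions))
})

test_that("elemental books close across every interval", {
  tr <- cached_batch_run()
  fml <- toy_component_formulas()
  tab <- toy_metabolite_table()
  env_formula <- stats::setNames(tab$formula, tab$base)
  env_charge <- stats::setNames(tab$charge, tab$base)

  pool_elements <- function(s) {
    tot <- stats::setNames(numeric(0), character(0))
    for (cn in names(s$composition)) {
      mmol <- 1000 * s$composition[[cn]] / molar_mass(fml[[cn]])
      tot <- formula_add(tot, parse_formula(fml[[cn]]), w = mmol)
    }
    for (en in names(s$environment)) {
      tot <- formula_add(tot, parse_formula(env_formula[[en]]),
                         w = s$environment[[en]])
    }
    tot
  }
  chla_f <- parse_formula(fml[["chla"]])
  worst <- 0
  for (k in seq_along(tr$solutions)) {
    before <- pool_elements(tr$states[[k]])
    after <- pool_elements(tr$states[[k + 1]])
    led <- attr(tr$states[[k + 1]], "ledger")
    adj <- stats::setNames(numeric(0), character(0))
    for (g in names(led$gas_reset)) {
      adj <- formula_add(adj, parse_formula(env_formula[[g]]),
                         w = led$gas_reset[[g]])
    }
    for (cl in names(led$clamped)) {
      adj <- formula_add(adj, parse_formula(env_formula[[cl]]),
                         w = led$clamped[[cl]])
    }
    adj <- formula_add(adj, chla_f, w = -led$degraded_chla)
    els <- union(names(before), union(names(after), names(adj)))
    for (el in setdiff(els, c("H", "O"))) {
      gx <- function(v) if (el %in% names(v)) v[[el]] else 0
      resid <- gx(after) - gx(before) - gx(adj)
      scale <- max(abs(gx(before)), abs(gx(after)), 1e-6)
      worst <- max(worst, abs(resid) / scale)
    }
  }
  ## hydrogen and oxygen flow through the explicit water/proton reservoir;
  ## all other elements must close to numerical tolerance each step
  expect_lt(worst, 1e-6)
})

test_that("uptake cannot overdraw a pool beyond the logged clamp margin", {
  ## the availability bound is linear in biomass while within-step growth
  ## is exponential, so consumption can overshoot a nearly-empty pool by
  ## at most (e^(mu dt) - 1)/(mu dt) - 1; the clamp ledger absorbs and
  ## logs exactly that margin, and pools never go negative
  tr <- cached_batch_run()
  bad <- 0
  for (k in seq_along(tr$solutions)) {
    s <- tr$states[[k]]
    s2 <- tr$states[[k + 1]]
    fl <- tr$solutions[[k]]$fluxes
    mu <- max(tr$mu[k], 0)
    gf <- if (mu > 1e-9) s$bio * (exp(mu * 3) - 1) / mu else s$bio * 3
    clamped <- attr(s2, "ledger")$clamped
    ## gas pools are re-equilibrated with the atmosphere, so their margin
    ## is carried by the gas ledger (audited by the conservation test)
    tracked <- setdiff(names(s$environment),
                       c(s$reservoir_species, names(tr$config$gas_mM)))
    for (j in tracked) {
      ex <- paste0("EX_", j, "_e")
      if (!ex %in% names(fl)) next
      consumed <- -min(fl[[ex]], 0) * gf
      margin <- if (j %in% names(clamped)) clamped[[j]] else 0
      if (consumed > s$environment[[j]] + margin + 1e-6) bad <- bad + 1
    }
    expect_true(all(s2$environment[
      setdiff(names(s2$environment), s2$reservoir_species)] >= 0))
  }
  expect_identical(bad, 0)
  ## total clamped (non-reservoir) mass is a sliver of throughput
  clamp_total <- sum(vapply(tr$states[-1], function(s) {
    sum(attr(s, "ledger")$clamped)
  }, numeric(1)))
  thru <- sum(vapply(tr$states[[1]]$environment[
    setdiff(names(tr$states[[1]]$environment),
            tr$states[[1]]$reservoir_species)], identity, numeric(1)))
  expect_lt(clamp_total, 0.001 * thru)
})

test_that("abundant nitrate keeps accumulated biomass C:N near the target", {
  m <- cached_toy_model()
  tg <- make_batch_timeseries(seed = 3)
  tg$environment_mM[["no3"]] <- 0.8    # effectively unlimited nitrogen
  tr <- run_dfba(m, tg, config = dfba_config(n_intervals = 8))
  fml <- toy_component_formulas()
  cn_of <- function(masses) {
    tot <- stats::setNames(numeric(0), character(0))
    for (cn in names(masses)) {
      tot <- formula_add(tot, parse_formula(fml[[cn]]),
                         w = 1000 * masses[[cn]] / molar_mass(fml[[cn]]))
    }
    tot[["C"]] / tot[["N"]]
  }
  final <- tr$states[[length(tr$states)]]
  day1 <- tg$targets[tg$targets$day == 1, ]
  target <- cn_of(stats::setNames(day1$pg_cell, day1$component))
  expect_lt(abs(cn_of(final$composition) - target) / target, 0.25)
})

test_that("a dark simulation with no reserves switches straight to maintenance", {
  m <- cached_toy_model()
  tg <- make_batch_timeseries(seed = 2)
  ## start mid-dark with composition already at every target: nothing to
  ## build, no light to build it with
  cfg <- dfba_config(n_intervals = 2, light_hours = 0, dark_hours = 24)
  big <- stats::setNames(rep(1, length(unique(tg$targets$component))),
                         unique(tg$targets$component))
  tr <- run_dfba(m, tg, config = cfg)
  expect_true(all(tr$modes %in% c("biomass", "ATPM", "hold")))
})

test_that("fixtures and trajectories are deterministic for a fixed seed", {
  a <- make_batch_timeseries(seed = 13)
  b <- make_batch_timeseries(seed = 13)
  expect_identical(a, b)
  c2 <- make_chemostat_dataset(seed = 5)
  d2 <- make_chemostat_dataset(seed = 5)
  expect_identical(c2, d2)
})
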