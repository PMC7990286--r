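test_that("FBA solves the single-path chain at its bound", {
  sol <- solve_fba(chain_model())
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes[c("EX_A", "R1", "EX_B")]), c(10, 10, 10))
  expect_lt(sol$max_abs_sv, 1e-6)
})

test_that("FBA matches the vertex-enumeration oracle on small networks", {
  m <- parallel_model()
  want <- enum_fba_optimum(m)
  got <- solve_fba(m)
  expect_true(want$feasible)
  expect_equal(got$objective_value, want$optimum, tolerance = 1e-8)

  set.seed(21)
  for (trial in 1:20) {
    n_m <- sample(2:3, 1); n_r <- sample(4:6, 1)
    mets <- lapply(seq_len(n_m), function(i)
      metabolite(paste0("m", i), compartment = "c"))
    rxns <- lapply(seq_len(n_r), function(j) {
      k <- sample(1:min(2, n_m), 1)
      ids <- sample(paste0("m", seq_len(n_m)), k)
      st <- stats::setNames(sample(c(-1, 1, -2, 2), k, TRUE), ids)
      reaction(paste0("r", j), st,
               lower_bound = sample(c(0, -3), 1), upper_bound = 5)
    })
    obj <- stats::setNames(1, "r1")
    mod <- metabolic_model(mets, rxns, objective = obj)
    want <- enum_fba_optimum(mod)
    got <- solve_fba(mod)
    if (want$feasible) {
      expect_identical(got$status, "optimal")
      expect_equal(got$objective_value, want$optimum, tolerance = 1e-7)
    }
  }
})

test_that("infeasible forced demand is reported as infeasible", {
  m <- chain_model()
  m <- set_bounds(m, "EX_A", 0, 0)
  m <- set_bounds(m, "EX_B", 1, 10)
  expect_identical(solve_fba(m)$status, "infeasible")
})

test_that("an empty objective is a configuration error", {
  m <- chain_model(); m$objective <- numeric(0)
  expect_error(solve_fba(m), "empty objective")
})

test_that("pFBA routes flux over the shorter of two equal-yield paths", {
  sol <- solve_pfba(parallel_model())
  expect_equal(sol$objective_value, 5, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes[["direct"]]), 5, tolerance = 1e-6)
  expect_lt(abs(sol$fluxes[["via1"]]), 1e-6)
})

test_that("pFBA keeps the phase-1 optimum and minimizes total flux", {
  m <- parallel_model()
  want <- enum_fba_optimum(m)
  sol <- solve_pfba(m)
  expect_equal(sol$objective_value, want$optimum, tolerance = 1e-5)
  ## parsimony dominates every enumerated alternate optimum
  for (v in want$vertices_at_optimum) {
    expect_lte(sol$sum_abs_flux, sum(abs(v)) + 1e-6)
  }
})

test_that("pFBA zeroes futile loops disconnected from the objective", {
  sol <- solve_pfba(loop_model())
  expect_equal(unname(sol$fluxes[c("L1", "L2", "L3")]), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("pFBA total flux never exceeds plain FBA's on random networks", {
  set.seed(33)
  for (trial in 1:20) {
    n_m <- sample(2:3, 1); n_r <- sample(5:6, 1)
    mets <- lapply(seq_len(n_m), function(i)
      metabolite(paste0("m", i), compartment = "c"))
    rxns <- lapply(seq_len(n_r), function(j) {
      k <- sample(1:min(2, n_m), 1)
      ids <- sample(paste0("m", seq_len(n_m)), k)
      st <- stats::setNames(sample(c(-1, 1), k, TRUE), ids)
      reaction(paste0("r", j), st, sample(c(0, -4), 1), 6)
    })
    mod <- metabolic_model(mets, rxns, objective = c(r1 = 1))
    fba <- solve_fba(mod)
    if (fba$status != "optimal") next
    pfba <- solve_pfba(mod)
    expect_identical(pfba$status, "optimal")
    expect_equal(pfba$objective_value, fba$objective_value,
                 tolerance = 1e-5)
    expect_lte(pfba$sum_abs_flux, fba$sum_abs_flux + 1e-6)
    expect_lt(pfba$max_abs_sv, 1e-6)
  }
})

test_that("flux-sum constraints shape solutions and removal restores them", {
  m <- parallel_model()
  base <- solve_fba(m)$objective_value
  ## equality tie: both routes carry the same flux
  m2 <- add_flux_constraint(m, flux_constraint(c(direct = 1, via1 = -1),
                                               0, 0, id = "tie"))
  s2 <- solve_pfba(m2)
  expect_equal(unname(s2$fluxes[["direct"]]), unname(s2$fluxes[["via1"]]),
               tolerance = 1e-8)
  expect_equal(s2$objective_value, base, tolerance = 1e-6)
  ## removal restores the original optimum
  m3 <- remove_flux_constraint(m2, "tie")
  expect_equal(solve_fba(m3)$objective_value, base, tolerance = 1e-9)
  ## unknown reaction id is named in the error
  expect_error(
    add_flux_constraint(m, flux_constraint(c(nope = 1), 0, 1)), "nope")
})

test_that("a binding lower bound on a flux sum forces flux", {
  m <- parallel_model()
  m <- add_flux_constraint(m, flux_constraint(c(via2 = 1), lower = 2))
  s <- solve_fba(m)
  expect_gte(s$fluxes[["via2"]], 2 - 1e-8)
})

test_that("energy-generating cycle detection flags a constructed loop", {
  m <- cached_toy_model()
  clean <- detect_energy_generating_cycles(m)
  expect_false(clean$ATPM$cycle)
  expect_lt(clean$ATPM$objective_value, 1e-6)

  ## an apyrase-style shortcut regenerating ATP for free creates a cycle
  bad <- add_reaction(m, reaction(
    "ATPSHORT", c(adp_c = -1, pi_c = -1, h_c = -1, atp_c = 1, h2o_c = 1),
    lower_bound = -1000, upper_bound = 1000))
  det <- detect_energy_generating_cycles(bad)
  expect_true(det$ATPM$cycle)
  expect_true("ATPSHORT" %in% det$ATPM$implicated)

  ## the repair pattern: capping the culprit's bound removes the cycle
  fixed <- set_bounds(bad, "ATPSHORT", 0, 0)
  expect_false(detect_energy_generating_cycles(fixed)$ATPM$cycle)

  ## a model with no declared dissipation reaction is a config error
  expect_error(detect_energy_generating_cycles(chain_model()),
               "dissipation")
})

test_that("mass/charge balance checking flags deficits and exemptions", {
  mets <- list(
    metabolite("h2o", formula = "H2O", compartment = "c"),
    metabolite("co2", formula = "CO2", compartment = "c"),
    metabolite("h2co3", formula = "H2CO3", compartment = "c"),
    metabolite("h2", formula = "H2", compartment = "c"),
    metabolite("mys", formula = NA_character_, compartment = "c"))
  rxns <- list(
    reaction("hydr", c(h2o = -1, co2 = -1, h2co3 = 1), 0, 10),
    reaction("split", c(h2o = -1, h2 = 1), 0, 10),
    reaction("EX_co2", c(co2 = -1), -10, 10),
    reaction("unk", c(mys = -1, h2 = 1), 0, 10))
  m <- metabolic_model(mets, rxns, objective = c(hydr = 1))
  rep <- check_mass_charge_balance(m)
  expect_true(rep$balanced[rep$reaction == "hydr"])
  expect_false(rep$balanced[rep$reaction == "split"])
  expect_equal(rep$detail[[which(rep$reaction == "split")]][["O"]], -1)
  expect_true(rep$exempt[rep$reaction == "EX_co2"])
  expect_false(rep$verifiable[rep$reaction == "unk"])
})

test_that("every non-exempt reaction of the mini-phototroph is balanced", {
  rep <- check_mass_charge_balance(cached_toy_model())
  bad <- rep[!rep$balanced & !rep$exempt, ]
  expect_identical(nrow(bad), 0L)
})

test_that("optimal solutions satisfy steady state and bounds", {
  m <- cached_toy_model()
  sol <- solve_pfba(m)
  expect_identical(sol$status, "optimal")
  expect_lt(sol$max_abs_sv, 1e-6)
  bd <- get_bounds(m)
  expect_true(all(sol$fluxes >= bd$lower - 1e-6))
  expect_true(all(sol$fluxes <= bd$upper + 1e-6))
})

test_that("the model summary reports network counts", {
  sm <- summary(cached_toy_model())
  expect_identical(sm$compartments, 6L)
  expect_gt(sm$reactions, 100)
  expect_gt(sm$genes, 50)
})
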