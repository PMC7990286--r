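test_that("biomass coefficients are millimolar contributions to 1 gDW", {
  r1 <- build_biomass_objective(
    biomass_composition(c(glc = 1), "gDW"),
    c(glc = "C6H12O6"), c(glc = "glc_c"))
  ## Mr(C6H12O6) = 180.156; spec arithmetic with Mr 100 via a pure-C unit
  r2 <- build_biomass_objective(
    biomass_composition(c(u = 1), "gDW"),
    c(u = "C8H4O2"),                       # Mr = 100.12
    c(u = "u_c"))
  expect_equal(-r2$stoichiometry[["u_c"]], 1000 / molar_mass("C8H4O2"),
               tolerance = 1e-12)

  r3 <- build_biomass_objective(
    biomass_composition(c(a = 0.6, b = 0.4), "gDW"),
    c(a = "C6H12O6", b = "C24H38O17"),     # Mr 180.156 / ~574.6
    c(a = "a_c", b = "b_c"))
  expect_equal(-r3$stoichiometry[["a_c"]], 1000 * 0.6 / molar_mass("C6H12O6"))
  expect_equal(-r3$stoichiometry[["b_c"]], 1000 * 0.4 / molar_mass("C24H38O17"))

  ## mass closure: coefficients weighted by molar mass give back 1 g
  expect_equal(-r1$stoichiometry[["glc_c"]] * molar_mass("C6H12O6") / 1000,
               1, tolerance = 1e-9)
  expect_equal(-(r3$stoichiometry[["a_c"]] * molar_mass("C6H12O6") +
                   r3$stoichiometry[["b_c"]] * molar_mass("C24H38O17")) / 1000,
               1, tolerance = 1e-9)
})

test_that("per-cell composition converts via its own dry weight, residual to frustule", {
  cs <- make_chemostat_dataset(seed = 1)
  low <- cs$compositions[cs$compositions$condition == 5, ]
  comp <- biomass_composition(
    stats::setNames(low$pg_cell, low$component), "pg_cell")
  g <- as_gdw_composition(comp)
  expect_equal(sum(g$masses), 1, tolerance = 1e-9)
  expect_equal(unname(g$masses[["frustule"]]), 5.2 / 22.4, tolerance = 1e-6)

  ## with a measured dry weight, the residual is assigned to the frustule
  no_frus <- comp$masses[setdiff(names(comp$masses), "frustule")]
  g2 <- as_gdw_composition(biomass_composition(no_frus, "pg_cell"),
                           total_dry_weight = 22.4)
  expect_equal(unname(g2$masses[["frustule"]]), 5.2 / 22.4, tolerance = 1e-6)
})

test_that("frustule condensation chemistry releases 2q water per Si", {
  f1 <- frustule_reaction(1)
  expect_equal(f1$reaction$stoichiometry[["h2o_c"]], 2)
  expect_identical(f1$unit_formula, "O2Si")
  expect_equal(f1$unit_mr, 60.083, tolerance = 1e-3)

  f0 <- frustule_reaction(0)
  expect_false("h2o_c" %in% names(f0$reaction$stoichiometry))
  expect_equal(f0$unit_mr, molar_mass("H4O4Si"))

  f75 <- frustule_reaction(0.75)
  expect_equal(f75$reaction$stoichiometry[["h2o_c"]], 1.5)
  expect_identical(f75$unit_formula, "HO2.5Si")   # SiO1.5(OH)1
  ## elemental books close: Si(OH)4 = unit + 1.5 H2O
  lhs <- parse_formula("H4O4Si")
  rhs <- formula_add(parse_formula(f75$unit_formula),
                     parse_formula("H2O"), w = 1.5)
  expect_equal(lhs[sort(names(lhs))], rhs[sort(names(rhs))])
  expect_error(frustule_reaction(1.2), "\\[0, 1\\]")
})

test_that("Si/C maps: linear under light limitation, power law under N limitation", {
  expect_equal(silica_per_cell(0, "light_limited",
                               list(slope = -2, intercept = 0.3)), 0.3)
  expect_equal(silica_per_cell(1, "N_limited", list(a = 0.07, k = -0.3)),
               0.07)
  ## slower light-limited growth carries a heavier frustule
  expect_gt(silica_per_cell(0.01, "light_limited"),
            silica_per_cell(0.05, "light_limited"))
})

test_that("degree of reduction: known values and linearity", {
  expect_identical(degree_of_reduction("CH2O", "nitrate"), 4)
  expect_identical(degree_of_reduction("CH2O", "ammonia"), 4)
  expect_identical(degree_of_reduction("CH4"), 8)
  ## nitrate vs ammonia reference differ by 8 electrons per N
  f <- "C5H8NO4"
  expect_equal(degree_of_reduction(f, "nitrate") -
                 degree_of_reduction(f, "ammonia"), 8 / 5)
  ## linear in formula entries
  a <- parse_formula("C2H6O"); b <- parse_formula("C3H4O3")
  ab <- formula_add(a, b)
  expect_equal(degree_of_reduction(ab) * ab[["C"]],
               degree_of_reduction(a) * a[["C"]] +
                 degree_of_reduction(b) * b[["C"]])
  expect_error(degree_of_reduction("H2O"), "carbon")
})

test_that("photosynthetic quotients follow the electron balance", {
  expect_equal(photosynthetic_quotient("CH2O", "ammonium"), 1)
  expect_equal(photosynthetic_quotient("CH2O", "nitrate"), 1)
  expect_equal(photosynthetic_quotient("CH2", "ammonium"), 1.5)
  ## PQ(NO3) - PQ(NH4) = 2 N/C exactly, across random formulas
  set.seed(5)
  for (i in 1:25) {
    cc <- sample(2:20, 1)
    ct <- c(C = cc, H = sample(cc:(2 * cc + 4), 1),
            O = sample(0:cc, 1), N = sample(1:min(cc, 6), 1))
    f <- format_formula(ct)
    pq_no3 <- photosynthetic_quotient(f, "nitrate")
    pq_nh4 <- photosynthetic_quotient(f, "ammonium")
    expect_equal(pq_no3 - pq_nh4, 2 * ct[["N"]] / ct[["C"]],
                 tolerance = 1e-12)
    expect_gte(pq_no3, pq_nh4)
  }
  ## a composite lies between its most-oxidized and most-reduced parts
  parts <- c(carb = "C6H12O6", lipid = "C55H98O6")
  pqs <- vapply(parts, photosynthetic_quotient, numeric(1),
                n_source = "ammonium")
  mix <- formula_add(parse_formula(parts[1]), parse_formula(parts[2]))
  pq_mix <- photosynthetic_quotient(mix, "ammonium")
  expect_gte(pq_mix, min(pqs) - 1e-12)
  expect_lte(pq_mix, max(pqs) + 1e-12)
})

test_that("generated biomass reactions close to 1 g within 1e-6", {
  for (acc in c("low", "medium", "high")) {
    comp <- toy_biomass_composition(acc)
    bof <- build_biomass_objective(
      biomass_composition(comp, "gDW"), toy_component_formulas(),
      toy_component_metabolites(), gam = 30)
    st <- bof$stoichiometry
    fml <- toy_component_formulas()
    met2comp <- stats::setNames(names(toy_component_metabolites()),
                                toy_component_metabolites())
    mass <- 0
    for (id in names(st)) {
      if (id %in% names(met2comp)) {
        mass <- mass - st[[id]] * molar_mass(fml[[met2comp[[id]]]]) / 1000
      }
    }
    expect_equal(mass, 1, tolerance = 1e-6)
  }
})

test_that("a missing component formula is reported by name", {
  expect_error(
    build_biomass_objective(biomass_composition(c(x = 1), "gDW"),
                            c(y = "CH2O")),
    "x")
})
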