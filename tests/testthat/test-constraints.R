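test_that("the CEF cap holds with equality when CEF is maximized", {
  m <- make_toy_phototroph_model(light_intensity = 2000)  # saturating
  m <- add_flux_constraint(m, cef_constraint(m, 0.05))
  s <- solve_fba(m, objective = c(CEF = 1))
  expect_identical(s$status, "optimal")
  fl <- s$fluxes
  tef <- fl[["PSICS"]] + fl[["PSIICS"]] - 2 * fl[["CBFC2"]] + 2 * fl[["CEF"]]
  expect_equal(2 * fl[["CEF"]] / tef, 0.05, tolerance = 1e-6)
})

test_that("a zero CEF fraction forces cyclic flow to zero", {
  m <- cached_toy_model()
  m <- add_flux_constraint(m, cef_constraint(m, 0))
  s <- solve_fba(m, objective = c(CEF = 1))
  expect_lt(abs(s$objective_value), 1e-8)
  expect_error(cef_constraint(m, 1), "\\[0, 1\\)")
})

test_that("every feasible solution respects the linearized CEF inequality", {
  m <- cached_toy_model()
  m <- add_flux_constraint(m, cef_constraint(m, 0.05))
  for (objid in c("DM_biomass_c", "CEF", "ATPM")) {
    s <- solve_pfba(m, objective = stats::setNames(1, objid))
    if (s$status != "optimal") next
    fl <- s$fluxes
    lhs <- 2 * fl[["CEF"]]
    rhs <- 0.05 * (fl[["PSICS"]] + fl[["PSIICS"]] - 2 * fl[["CBFC2"]] +
                     2 * fl[["CEF"]])
    expect_lte(lhs, rhs + 1e-7)
  }
})

test_that("a cap derived at saturating light binds harder at low light", {
  sat <- make_toy_phototroph_model(light_intensity = 2000)
  sat <- add_flux_constraint(sat, cef_constraint(sat, 0.05))
  cap <- solve_fba(sat, objective = c(CEF = 1))$objective_value
  expect_gt(cap, 0)
  ## reuse the absolute cap at low light: CEF can now be a large share of
  ## the (much smaller) total electron flow
  low <- make_toy_phototroph_model(light_intensity = 10)
  low <- set_bounds(low, "CEF", 0, cap)
  s <- solve_fba(low, objective = c(CEF = 1))
  fl <- s$fluxes
  tef <- fl[["PSICS"]] + fl[["PSIICS"]] - 2 * fl[["CBFC2"]] + 2 * fl[["CEF"]]
  expect_gt(2 * fl[["CEF"]] / tef, 0.05)
})

test_that("photorespiration ratio follows specificity and gas concentrations", {
  r <- photorespiration_ratio(79, 100, 200)
  expect_equal(r$vc_vo, 39.5)
  expect_equal(r$ratio, 0.025)
  expect_equal(r$ratio_raw, 1 / 39.5)

  expect_message(r0 <- photorespiration_ratio(79, 100, 0), "zero")
  expect_identical(r0$ratio, 0)

  expect_equal(photorespiration_ratio(50, 100, 100)$ratio, 0.020)

  ## monotonicity: more O2 raises it, more CO2 or specificity lowers it
  base <- photorespiration_ratio(79, 100, 200)$ratio_raw
  expect_gt(photorespiration_ratio(79, 100, 300)$ratio_raw, base)
  expect_lt(photorespiration_ratio(79, 200, 200)$ratio_raw, base)
  expect_lt(photorespiration_ratio(100, 100, 200)$ratio_raw, base)
})

test_that("the photorespiration constraint couples oxygenase to carboxylase", {
  m <- cached_toy_model()
  m1 <- add_flux_constraint(m, photorespiration_constraint(m, ratio = 0.025))
  s <- solve_pfba(m1)
  expect_equal(unname(s$fluxes[["RUBISO_h"]]),
               0.025 * unname(s$fluxes[["RUBISC_h"]]), tolerance = 1e-7)
  ## interval form for dynamic runs
  m2 <- m
  for (ct in photorespiration_constraint(m, range = c(0.001, 0.025))) {
    m2 <- add_flux_constraint(m2, ct)
  }
  s2 <- solve_pfba(m2)
  ratio <- s2$fluxes[["RUBISO_h"]] / s2$fluxes[["RUBISC_h"]]
  expect_gte(ratio, 0.001 - 1e-9)
  expect_lte(ratio, 0.025 + 1e-9)
})

test_that("energetic coupling ties mitochondrial NADH oxidation to PSI", {
  m <- cached_toy_model()
  m1 <- add_flux_constraint(m, energetic_coupling_constraint(m, 0.0015))
  s <- solve_pfba(m1)
  expect_identical(s$status, "optimal")
  expect_equal(unname(s$fluxes[["NADHOR_m"]]),
               0.0015 * unname(s$fluxes[["PSICS"]]), tolerance = 1e-7)
  ## PSI runs, so the mitochondrial chain must carry flux
  expect_gt(s$fluxes[["PSICS"]], 0)
  expect_gt(s$fluxes[["NADHOR_m"]], 0)
  expect_gt(s$fluxes[["AOX_m"]] + s$fluxes[["CYOO_m"]], 0)
  expect_error(energetic_coupling_constraint(m, -1), ">= 0")
})

test_that("strong energetic coupling costs growth at low light", {
  m <- make_toy_phototroph_model(light_intensity = 10)
  m <- add_flux_constraint(m, cef_constraint(m, 0.05))
  mu0 <- solve_fba(add_flux_constraint(
    m, energetic_coupling_constraint(m, 0)))$objective_value
  mu_hi <- solve_fba(add_flux_constraint(
    m, energetic_coupling_constraint(m, 0.05)))
  mu_hi <- if (mu_hi$status == "optimal") mu_hi$objective_value else 0
  expect_lt(mu_hi, mu0 + 1e-9)
})

test_that("respiration flux-sum constraints bound the oxidase pool", {
  m <- cached_toy_model()
  base <- solve_fba(m)$objective_value
  ## zero measurement: vacuous, optimum unchanged
  cts0 <- respiration_constraints(m, 0, c(0, 1000))
  m0 <- m; for (ct in cts0) m0 <- add_flux_constraint(m0, ct)
  expect_equal(solve_fba(m0)$objective_value, base, tolerance = 1e-8)

  ## a binding lower bound forces oxidase flux
  cts <- respiration_constraints(m, 1, c(0, 1000))
  m1 <- m; for (ct in cts) m1 <- add_flux_constraint(m1, ct)
  s <- solve_pfba(m1)
  w <- toy_category_map()$o2_reducing
  expect_gte(sum(w * abs(s$fluxes[names(w)])), 1 - 1e-7)

  ## tightening the TCA window shifts flux without killing growth
  cts2 <- respiration_constraints(m, 1, c(0.05, 0.08))
  m2 <- m; for (ct in cts2) m2 <- add_flux_constraint(m2, ct)
  s2 <- solve_pfba(m2)
  expect_identical(s2$status, "optimal")
  tca <- toy_category_map()$tca_dehydrogenase
  expect_gte(sum(tca * abs(s2$fluxes[names(tca)])), 0.05 - 1e-7)
  expect_lte(sum(tca * abs(s2$fluxes[names(tca)])), 0.08 + 1e-7)
  expect_gt(s2$objective_value, 0)

  expect_error(respiration_constraints(m, 1, c(0, 1),
                                       list(o2_reducing = numeric(0),
                                            tca_dehydrogenase = c(TCADH_m = 3))),
               "empty")
})

test_that("PSII bounds are the delta-method confidence band of the fit", {
  I <- c(2, 5, 10, 20, 40, 80, 160, 320)
  gpp <- 5 * (1 - exp(-0.1 * I / 5))
  fit <- fit_platt(I, gpp)
  ## noiseless fit: covariance ~ 0, bounds collapse onto the prediction
  b <- psii_bounds_from_fit(fit, 60)
  expect_equal(unname(b[["lb"]]), unname(b[["ub"]]), tolerance = 1e-4)
  expect_equal(unname(b[["ub"]]), predict(fit, 60), tolerance = 1e-4)

  ## hand-computed delta method on a synthetic covariance
  fit2 <- fit
  fit2$vcov <- matrix(c(0.04, 0.001, 0.001, 1e-4), 2, 2,
                      dimnames = list(c("Ps", "alpha"), c("Ps", "alpha")))
  p <- coef(fit2); I0 <- 60
  g <- c(Ps = 1 - exp(-p[["alpha"]] * I0 / p[["Ps"]]) -
           (p[["alpha"]] * I0 / p[["Ps"]]) * exp(-p[["alpha"]] * I0 / p[["Ps"]]),
         alpha = I0 * exp(-p[["alpha"]] * I0 / p[["Ps"]]))
  se <- sqrt(drop(t(g) %*% fit2$vcov %*% g))
  tq <- stats::qt(0.975, fit2$df)
  want <- predict(fit2, I0) + c(-1, 1) * tq * se
  got <- psii_bounds_from_fit(fit2, I0)
  expect_equal(unname(got), want, tolerance = 1e-5)

  ## wider parameter uncertainty, wider band
  fit3 <- fit2; fit3$vcov <- fit2$vcov * 4
  got3 <- psii_bounds_from_fit(fit3, I0)
  expect_gt(got3[["ub"]] - got3[["lb"]], got[["ub"]] - got[["lb"]])
  expect_error(psii_bounds_from_fit(fit, -5), ">= 0")
})

test_that("transient carbon sinks split catabolism by dividing fraction", {
  m <- cached_toy_model()
  m1 <- transient_carbon_sinks(m, catabolism = 1.2, dividing_fraction = 1)
  expect_equal(m1$reactions$SK_chryso_c$lower_bound, -1.2 / 6)
  expect_equal(m1$reactions$SK_g3p_c$lower_bound, 0)
  m0 <- transient_carbon_sinks(m, 1.2, 0)
  expect_equal(m0$reactions$SK_chryso_c$lower_bound, 0)
  expect_equal(m0$reactions$SK_g3p_c$lower_bound, -1.2 / 3)
  m3 <- transient_carbon_sinks(m, 1.2, 0.3)
  cweight <- 6 * abs(m3$reactions$SK_chryso_c$lower_bound) +
    3 * abs(m3$reactions$SK_g3p_c$lower_bound)
  expect_equal(cweight, 1.2, tolerance = 1e-12)
  expect_error(transient_carbon_sinks(m, 1, 1.5), "\\[0, 1\\]")
})
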