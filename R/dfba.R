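## Dynamic FBA for batch-culture nitrogen starvation: per-interval biomass
## objectives from target compositions, Michaelis-Menten/availability
## uptake bounds, remobilization sinks, photosynthetic-quotient coupling,
## and exponential state updates between quasi-steady-state pFBA solves.

#' Dynamic-FBA state
#'
#' @param t time (h).
#' @param composition named numeric, biomass component -> g/L.
#' @param environment named numeric, environment metabolite -> mM.
#' @param reservoir_species environment entries representing buffered,
#'   effectively infinite pools (the water solvent, pH-buffered protons):
#'   they track net exchange and may run negative.
#' @return object of class `"dfba_state"`; `bio` (total g/L) and
#'   `chl_ratio` (mg chl a per gDW) are derived fields.
#' @export
dfba_state <- function(t, composition, environment,
                       reservoir_species = c("h2o", "h")) {
  res <- names(environment) %in% reservoir_species
  stopifnot(all(composition >= -1e-12), all(environment[!res] >= -1e-9))
  bio <- sum(composition)
  chl <- if ("chla" %in% names(composition) && bio > 0) {
    1000 * composition[["chla"]] / bio
  } else 0
  env <- environment
  env[!res] <- pmax(env[!res], 0)
  structure(list(t = t, bio = bio, composition = pmax(composition, 0),
                 environment = env, reservoir_species = reservoir_species,
                 chl_ratio = chl),
            class = "dfba_state")
}

#' Default Michaelis-Menten uptake kinetics
#'
#' Literature-style parameters for the major nutrients; every other
#' exchanged metabolite gets `Vmax = 0.2`, `Km = 0.05`, and freely
#' diffusing water and protons get `Vmax = 1000` (effectively
#' unrestricted).
#'
#' @return data frame: `metabolite`, `Vmax` (mmol gDW^-1 h^-1), `Km` (mM).
#' @export
default_uptake_kinetics <- function() {
  data.frame(
    metabolite = c("no3", "nh4", "pi", "sioh4", "so4", "co2", "hco3",
                   "o2", "mg2", "h2o", "h"),
    Vmax = c(0.5, 0.5, 0.1, 0.3, 1.0, 10, 10, 20, 1.0, 1000, 1000),
    Km = c(0.005, 0.002, 0.002, 0.02, 0.5, 0.03, 0.5, 0.01, 0.1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Dynamic-FBA configuration
#'
#' @param dt interval length (h).
#' @param n_intervals number of intervals.
#' @param light_hours,dark_hours photoperiod (h); the run starts at dawn.
#' @param intensity irradiance during the light period (umol photons m^-2
#'   s^-1).
#' @param pq_scale photosynthetic-quotient scaling explored around 1
#'   (values outside 0.9-1.1 draw a warning).
#' @param photoresp_range oxygenase:carboxylase flux interval.
#' @param cef_fraction CEF cap as a fraction of total electron flow.
#' @param gam growth-associated maintenance of the per-interval biomass
#'   reactions (mmol ATP gDW^-1).
#' @param ngam_params factors of the closed-form maintenance bound
#'   (`Ic`, `a_chl`, `phi_m`, `e`); the chl a : dry weight ratio comes from
#'   the simulated composition each interval.
#' @param gas_mM atmospheric-equilibrium concentrations that O2, CO2 and
#'   HCO3 are reset to after every interval (well-mixed, bubbled culture;
#'   390 ppm pCO2 carbonate values).
#' @param unit_scale factor applied to bounds/fluxes inside the solver
#'   (kept at 1; the LP core is scale-stable at these problem sizes).
#' @return list of class `"dfba_config"`.
#' @export
dfba_config <- function(dt = 3, n_intervals = 80, light_hours = 12,
                        dark_hours = 12, intensity = 85, pq_scale = 1.02,
                        photoresp_range = c(0.001, 0.025),
                        cef_fraction = 0.05, gam = 30,
                        ngam_params = list(Ic = 11, a_chl = 0.02,
                                           phi_m = 0.056, e = 3),
                        gas_mM = c(co2 = 0.0133, hco3 = 1.78, o2 = 0.21),
                        unit_scale = 1) {
  if (pq_scale < 0.9 || pq_scale > 1.1) {
    warning("pq_scale outside the explored 0.9-1.1 window")
  }
  structure(as.list(environment()), class = "dfba_config")
}

## linear interpolation helpers over the measurement days
interp_cells <- function(targets, day) {
  stats::approx(targets$days, targets$cells_per_L, xout = day, rule = 2)$y
}
interp_psii <- function(targets, day) {
  lb <- stats::approx(targets$psii$day, targets$psii$lb, xout = day,
                      rule = 2)$y
  ub <- stats::approx(targets$psii$day, targets$psii$ub, xout = day,
                      rule = 2)$y
  c(lb = lb, ub = ub)
}

#' Per-interval biomass objective from target compositions
#'
#' Computes, for the interval starting at `state$t`, the difference between
#' the next measured target composition (converted from pg/cell to g/L
#' with the interpolated cell count, and scaled by the light-period
#' fold-change `f` for diel storage compounds) and the current simulated
#' composition. Positive differences, normalized, become the biomass
#' objective fractions; components known to be consumed at night (pigments,
#' chrysolaminarin, triacylglycerides) are dropped from dark intervals. If
#' no component needs net production, the objective switches to ATP
#' maintenance.
#'
#' @param state a [dfba_state()].
#' @param targets a batch time series (see [make_batch_timeseries()]).
#' @param is_dark logical: dark interval?
#' @param dt interval length (h), used to locate the next target day.
#' @return list: `mode` (`"biomass"` or `"ATPM"`), `fractions` (named, sums
#'   to 1; empty in ATPM mode), `delta` (all signed differences, g/L),
#'   `target_day`.
#' @export
interval_objective <- function(state, targets, is_dark, dt = 3) {
  day_now <- state$t / 24
  nxt <- targets$days[targets$days > day_now + 1e-9]
  if (!length(nxt)) {
    stop("no future target day beyond t = ", state$t, " h; simulation ends")
  }
  tm <- nxt[1]
  cells_t2 <- interp_cells(targets, (state$t + dt) / 24)
  tg <- targets$targets[targets$targets$day == tm, ]
  target_gL <- stats::setNames(tg$pg_cell * cells_t2 * 1e-12, tg$component)
  if (!is_dark) {
    f <- targets$fold_change
    target_gL[names(f)] <- target_gL[names(f)] * f
  }
  comps <- union(names(target_gL), names(state$composition))
  cur <- stats::setNames(numeric(length(comps)), comps)
  cur[names(state$composition)] <- state$composition
  tgt <- stats::setNames(numeric(length(comps)), comps)
  tgt[names(target_gL)] <- target_gL
  delta <- tgt - cur
  pos <- delta[delta > 0]
  if (is_dark) pos <- pos[setdiff(names(pos), targets$dark_excluded)]
  if (!length(pos)) {
    return(list(mode = "ATPM", fractions = numeric(0), delta = delta,
                target_day = tm))
  }
  list(mode = "biomass", fractions = pos / sum(pos), delta = delta,
       target_day = tm)
}

#' Uptake lower bounds from kinetics and availability
#'
#' For each exchanged metabolite `j`,
#' `LB_j = -min(Vmax * x_j / (Km + x_j), x_j / (bio * dt))`: the
#' Michaelis-Menten rate, or the amount that would exhaust the pool within
#' one interval, whichever is closer to zero. A zero concentration gives a
#' zero bound.
#'
#' @param state a [dfba_state()] with `bio > 0`.
#' @param kinetics data frame as [default_uptake_kinetics()].
#' @param dt interval length (h), `> 0`.
#' @param free_species metabolites exempt from both limbs: water is the
#'   solvent and protons are buffered (seawater pH is held by the
#'   carbonate system), so neither is pool-limited; they get `-Vmax`
#'   (effectively unrestricted at 1000).
#' @return named numeric: exchange reaction id (`EX_<met>_e`) -> lower
#'   bound (mmol gDW^-1 h^-1, `<= 0`).
#' @export
uptake_bounds <- function(state, kinetics = default_uptake_kinetics(), dt = 3,
                          free_species = c("h2o", "h")) {
  stopifnot(dt > 0, state$bio > 0)
  x <- state$environment
  kv <- stats::setNames(kinetics$Vmax, kinetics$metabolite)
  kk <- stats::setNames(kinetics$Km, kinetics$metabolite)
  out <- vapply(names(x), function(j) {
    vmax <- if (j %in% names(kv)) kv[[j]] else 0.2
    if (j %in% free_species) return(-vmax)
    km <- if (j %in% names(kk)) kk[[j]] else 0.05
    mm <- vmax * x[[j]] / (km + x[[j]])
    avail <- x[[j]] / (state$bio * dt)
    -min(mm, avail)
  }, numeric(1))
  stats::setNames(out, paste0("EX_", names(x), "_e"))
}

#' Remobilization sink bounds for declining biomass components
#'
#' Components whose target is below the current simulated mass may be
#' remobilized: their sink reaction can supply up to the surplus,
#' `LB_j = delta_j * 1000 / Mr_j / (bio * dt)` (negative, mmol gDW^-1
#' h^-1). Chlorophyll a additionally gets a forced degradation demand
#' (its breakdown pathway is uncharacterized, so products are routed to a
#' demand) with lower bound equal to the decline.
#'
#' @param state a [dfba_state()].
#' @param delta signed component differences (g/L) from
#'   [interval_objective()].
#' @param component_formulas named formulas for molar masses.
#' @param dt interval length (h).
#' @param sink_map named character: component -> sink reaction id.
#' @param chla_demand id of the chlorophyll degradation demand reaction.
#' @return named numeric of reaction lower bounds (sinks negative, the
#'   chlorophyll demand positive).
#' @export
remobilization_bounds <- function(state, delta, component_formulas, dt = 3,
                                  sink_map = c(
                                    protein = "SK_protein_c",
                                    faa = "SK_faa_c", chryso = "SK_chryso_c",
                                    rna = "SK_rna_c", tag = "SK_tag_c",
                                    chitin = "SK_chitin_c",
                                    polyp = "SK_polyp_c", chla = "SK_chla_h"),
                                  chla_demand = "DM_chla_h") {
  neg <- delta[delta < 0]
  out <- numeric(0)
  for (comp in names(neg)) {
    if (comp %in% names(sink_map)) {
      if (!comp %in% names(component_formulas)) {
        stop("no molar mass for remobilized component: ", comp)
      }
      mr <- molar_mass(component_formulas[[comp]])
      out[sink_map[[comp]]] <- neg[[comp]] * 1000 / mr / (state$bio * dt)
    }
  }
  ## chlorophyll a degradation is forced (not optional): the demand's
  ## lower bound matches the sink supply, so the decline is realized
  if ("chla" %in% names(neg)) {
    out[chla_demand] <- -out[["SK_chla_h"]]
  }
  out
}

#' Photosynthetic-quotient coupling constraints
#'
#' Confines the ratio of O2 evolution to dissolved inorganic carbon
#' assimilation during a light interval to the window spanned by the
#' ammonium- and nitrate-based photosynthetic quotients of the new-biomass
#' formula, times `pq_scale`. Dark intervals are left unconstrained.
#'
#' @param new_biomass_formula atom counts (or formula string) of the
#'   interval's new biomass.
#' @param pq_scale scaling factor (0.95-1.05 is the explored range; values
#'   outside 0.9-1.1 draw a warning).
#' @param o2_id,dic_ids exchange reaction ids for O2 and DIC species.
#' @return list: `window` (`c(lo, hi)`), `constraints` (two
#'   [flux_constraint()]s, ids `pq_lo`/`pq_hi`).
#' @export
pq_bounds <- function(new_biomass_formula, pq_scale = 1, o2_id = "EX_o2_e",
                      dic_ids = c("EX_co2_e", "EX_hco3_e")) {
  if (pq_scale < 0.9 || pq_scale > 1.1) {
    warning("pq_scale outside the explored 0.9-1.1 window")
  }
  pq_nh4 <- photosynthetic_quotient(new_biomass_formula, "ammonium")
  pq_no3 <- photosynthetic_quotient(new_biomass_formula, "nitrate")
  w <- sort(c(pq_nh4, pq_no3)) * pq_scale
  ## O2 evolution = EX_o2 flux (positive out); DIC uptake = -(sum EX_dic)
  lo_cf <- stats::setNames(c(1, rep(w[1], length(dic_ids))),
                           c(o2_id, dic_ids))
  hi_cf <- stats::setNames(c(1, rep(w[2], length(dic_ids))),
                           c(o2_id, dic_ids))
  list(window = w, pq_nh4 = pq_nh4, pq_no3 = pq_no3,
       constraints = list(
         flux_constraint(lo_cf, lower = 0, upper = Inf, id = "pq_lo"),
         flux_constraint(hi_cf, lower = -Inf, upper = 0, id = "pq_hi")))
}

#' Advance the dynamic-FBA state by one interval
#'
#' Biomass grows exponentially at the realized growth rate mu (the biomass
#' demand flux): `bio(t2) = bio(t1) * exp(mu dt)`. Each environment
#' metabolite follows
#' `x_j(t2) = x_j(t1) + (v_j/mu) * bio(t1) * (exp(mu dt) - 1)`, with the
#' explicit-Euler limit `x_j + v_j * bio * dt` once `mu < 1e-9`. New
#' biomass is apportioned to components by the interval objective
#' fractions; remobilization sink fluxes drain their components. O2, CO2
#' and HCO3 are then reset to atmospheric equilibrium (continuously
#' bubbled, well-mixed culture) and any small negative environment pools
#' are clamped to zero; both adjustments are logged in the returned
#' state's `ledger` attribute (mmol/L).
#'
#' @param state a [dfba_state()].
#' @param sol an optimal `flux_solution` for the interval.
#' @param dt interval length (h).
#' @param fractions biomass objective fractions of the interval.
#' @param component_formulas named component formulas (for sink molar
#'   masses).
#' @param config a [dfba_config()] (gas reset values).
#' @param sink_map,chla_demand as in [remobilization_bounds()].
#' @param growth_id biomass demand reaction id.
#' @return the next [dfba_state()], with attribute `ledger` (named list of
#'   `gas_reset` and `clamped`, mmol/L).
#' @export
advance_state <- function(state, sol, dt, fractions, component_formulas,
                          config = dfba_config(),
                          sink_map = c(protein = "SK_protein_c",
                                       faa = "SK_faa_c",
                                       chryso = "SK_chryso_c",
                                       rna = "SK_rna_c", tag = "SK_tag_c",
                                       chitin = "SK_chitin_c",
                                       polyp = "SK_polyp_c",
                                       chla = "SK_chla_h"),
                          growth_id = "DM_biomass_c") {
  stopifnot(sol$status == "optimal")
  mu <- sol$fluxes[[growth_id]]
  if (mu < -1e-9) stop("negative growth flux: ", mu)
  mu <- max(mu, 0)
  bio1 <- state$bio
  growth_factor <- if (mu > 1e-9) bio1 * (exp(mu * dt) - 1) / mu else
    bio1 * dt
  bio2 <- bio1 * exp(mu * dt)

  ## environment: every exchange flux moves mass in/out of the medium
  env <- state$environment
  for (j in names(env)) {
    ex <- paste0("EX_", j, "_e")
    if (ex %in% names(sol$fluxes)) {
      ## exchange stoichiometry is met -> (nothing); positive flux secretes
      env[[j]] <- env[[j]] + sol$fluxes[[ex]] * growth_factor
    }
  }

  ## composition: new biomass by objective fraction, remobilization by
  ## sink flux
  comp <- state$composition
  if (length(fractions)) {
    gain <- (bio2 - bio1) * fractions
    for (k in names(gain)) {
      comp[k] <- (if (k %in% names(comp)) comp[[k]] else 0) + gain[[k]]
    }
  }
  for (cn in names(sink_map)) {
    sk <- sink_map[[cn]]
    if (sk %in% names(sol$fluxes) && abs(sol$fluxes[[sk]]) > 1e-12) {
      mr <- molar_mass(component_formulas[[cn]])
      comp[cn] <- (if (cn %in% names(comp)) comp[[cn]] else 0) +
        sol$fluxes[[sk]] * mr / 1000 * growth_factor
    }
  }
  comp <- pmax(comp, 0)

  ## chlorophyll degradation demand destroys mass (products unresolved);
  ## logged so elemental books still close
  degraded_chla <- if ("DM_chla_h" %in% names(sol$fluxes)) {
    sol$fluxes[["DM_chla_h"]] * growth_factor
  } else 0

  ## gas re-equilibration and clamping, with a mass ledger
  gas <- config$gas_mM
  gas_reset <- stats::setNames(numeric(length(gas)), names(gas))
  for (g in names(gas)) {
    gas_reset[g] <- gas[[g]] - env[[g]]
    env[[g]] <- gas[[g]]
  }
  res <- names(env) %in% state$reservoir_species
  clamped <- -pmin(env, 0)
  clamped[res] <- 0
  clamped <- clamped[clamped > 0]
  env[!res] <- pmax(env[!res], 0)

  out <- dfba_state(state$t + dt, comp, env,
                    reservoir_species = state$reservoir_species)
  attr(out, "ledger") <- list(gas_reset = gas_reset, clamped = clamped,
                              degraded_chla = degraded_chla)
  out
}

#' Run a dynamic-FBA batch simulation
#'
#' Loops [interval_objective()] -> bounds (uptake, remobilization,
#' photosynthetic quotient, photon absorption rebuilt from the simulated
#' pigment composition, PSII bounds converted from per-chlorophyll to
#' per-dry-weight units) -> parsimonious FBA -> [advance_state()] over the
#' configured time grid (default eighty 3-hour intervals under a 12:12
#' light:dark cycle). An infeasible interval falls back to the ATP
#' maintenance objective, then to a recorded zero-growth hold; it is never
#' silent.
#'
#' @param model a mini-phototroph-style model (see
#'   [make_toy_phototroph_model()]).
#' @param targets a batch time series from [make_batch_timeseries()].
#' @param kinetics uptake kinetics data frame.
#' @param config a [dfba_config()].
#' @param verbose print one line per interval.
#' @return object of class `"dfba_trajectory"`: `states` (list of
#'   [dfba_state()]), `solutions`, `modes`, `mu`, `feasible`, `config`.
#' @export
run_dfba <- function(model, targets, kinetics = default_uptake_kinetics(),
                     config = dfba_config(), verbose = FALSE) {
  comp_formulas <- toy_component_formulas()
  pig_spectra <- default_pigment_profile("medium")$spectra
  pig_eff <- default_pigment_profile("medium")$transfer_efficiency
  src <- default_light_source()

  ## permanent condition constraints
  model <- add_flux_constraint(model, cef_constraint(model,
                                                     config$cef_fraction))
  prc <- photorespiration_constraint(model, range = config$photoresp_range)
  for (ct in prc) model <- add_flux_constraint(model, ct)

  ## initial state: day-0 targets at the initial biomass
  tg0 <- targets$targets[targets$targets$day == 0, ]
  comp0 <- stats::setNames(tg0$pg_cell * targets$cells_per_L[1] * 1e-12,
                           tg0$component)
  comp0 <- comp0 * targets$initial_biomass_gL / sum(comp0)
  env0 <- c(targets$environment_mM,
            h2o = 55000, h = 1e-4,
            dmsp = 0, dhps = 0, etoh = 0, `for` = 0, ac = 0, glyclt = 0,
            glu__L = 0, gly = 0, no2 = 0, frus = 0)
  env0 <- env0[!duplicated(names(env0))]
  state <- dfba_state(0, comp0, env0)

  states <- list(state)
  solutions <- list(); modes <- character(0); mus <- numeric(0)
  feasible <- logical(0)

  for (k in seq_len(config$n_intervals)) {
    hour <- state$t %% (config$light_hours + config$dark_hours)
    is_dark <- hour >= config$light_hours
    obj <- tryCatch(interval_objective(state, targets, is_dark, config$dt),
                    error = function(e) NULL)
    if (is.null(obj)) break   # no future target: clean end of simulation

    m <- model
    ## per-interval biomass reaction (positive components only)
    if (obj$mode == "biomass") {
      bof <- build_biomass_objective(
        biomass_composition(obj$fractions, basis = "gDW"),
        comp_formulas, toy_component_metabolites(), gam = config$gam)
      m$reactions[["BIOMASS"]] <- bof
    }

    ## photon absorption rebuilt from simulated pigment composition
    pigs <- intersect(rownames(pig_spectra), names(state$composition))
    pig_frac <- stats::setNames(
      vapply(pigs, function(p) state$composition[[p]] / state$bio,
             numeric(1)), pigs)
    prof <- pigment_profile(pig_frac, pig_spectra[pigs, , drop = FALSE],
                            pig_eff)
    m <- build_light_reactions(m, prof, src,
                               if (is_dark) 0 else config$intensity)

    ## PSII bounds: per mg chl a -> per gDW with the simulated ratio;
    ## x4 converts mmol O2 to the reaction's single-electron units
    if (!is_dark) {
      pb <- interp_psii(targets, state$t / 24) * state$chl_ratio * 4
      m <- set_bounds(m, "PSIICS", pb[["lb"]], pb[["ub"]])
    } else {
      m <- set_bounds(m, "PSIICS", 0, 0)
    }

    ## uptake and remobilization bounds
    ub <- uptake_bounds(state, kinetics, config$dt)
    for (ex in names(ub)) {
      if (ex %in% names(m$reactions)) m <- set_bounds(m, ex, lower = ub[[ex]])
    }
    rb <- remobilization_bounds(state, obj$delta, comp_formulas, config$dt)
    for (rid in names(rb)) {
      if (!rid %in% names(m$reactions)) next
      if (rid == "DM_chla_h") {
        m <- set_bounds(m, rid, rb[[rid]], 1000)
      } else {
        m <- set_bounds(m, rid, rb[[rid]], 0)
      }
    }

    ## maintenance bound from the closed form at the simulated chl ratio
    np <- config$ngam_params
    atpm_ub <- max(ngam_upper_bound(np$Ic, np$a_chl, state$chl_ratio,
                                    np$phi_m, np$e), 1e-3)
    m <- set_bounds(m, "ATPM", 0, atpm_ub)

    ## photosynthetic quotient coupling (light only)
    if (!is_dark && obj$mode == "biomass") {
      newf <- stats::setNames(numeric(0), character(0))
      for (cn in names(obj$fractions)) {
        fc <- parse_formula(comp_formulas[[cn]])
        w <- 1000 * obj$fractions[[cn]] / molar_mass(comp_formulas[[cn]])
        newf <- formula_add(newf, fc, w = w)
      }
      ## carbon-free new biomass (e.g. a frustule-only interval) has no
      ## O2:DIC ratio to constrain
      if ("C" %in% names(newf) && newf[["C"]] > 0) {
        pq <- pq_bounds(newf, config$pq_scale)
        for (ct in pq$constraints) m <- add_flux_constraint(m, ct)
      }
    }

    mode <- obj$mode
    m1 <- set_objective(m, stats::setNames(
      1, if (mode == "biomass") "DM_biomass_c" else "ATPM"))
    sol <- solve_pfba(m1)
    if (sol$status != "optimal" && mode == "biomass") {
      mode <- "ATPM"
      sol <- solve_pfba(set_objective(m, c(ATPM = 1)))
    }
    if (sol$status != "optimal") {
      ## zero-growth hold: record the interval, advance time only
      mode <- "hold"
      sol <- new_flux_solution("optimal", 0, stats::setNames(
        rep(0, length(m$reactions)), names(m$reactions)))
    }

    state <- advance_state(state, sol, config$dt, obj$fractions,
                           comp_formulas, config)
    states[[k + 1L]] <- state
    solutions[[k]] <- sol
    modes[k] <- mode
    mus[k] <- if (mode == "hold") 0 else sol$fluxes[["DM_biomass_c"]]
    feasible[k] <- mode != "hold"
    if (verbose) {
      cat(sprintf("t=%5.0f h %s mode=%-7s mu=%.4f bio=%.4g no3=%.4g\n",
                  state$t, if (is_dark) "dark " else "light", mode, mus[k],
                  state$bio, state$environment[["no3"]]))
    }
  }

  structure(list(states = states, solutions = solutions, modes = modes,
                 mu = mus, feasible = feasible, config = config,
                 targets = targets),
            class = "dfba_trajectory")
}

#' @export
print.dfba_trajectory <- function(x, ...) {
  n <- length(x$solutions)
  cat("<dfba_trajectory> ", n, " intervals of ", x$config$dt, " h\n",
      sep = "")
  cat("  biomass: ", format(x$states[[1]]$bio, digits = 4), " -> ",
      format(x$states[[n + 1]]$bio, digits = 4), " g/L\n", sep = "")
  cat("  modes: ", paste(sprintf("%s:%d", names(table(x$modes)),
                                 table(x$modes)), collapse = "  "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a trajectory into a long data frame
#' @param x a `dfba_trajectory`.
#' @param row.names,optional,... unused (S3 signature).
#' @return data frame: `t` (h), `variable`, `value`; biomass components in
#'   g/L (prefix `comp_`), environment in mM (prefix `env_`), plus `bio`
#'   and `mu`.
#' @export
as.data.frame.dfba_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  rows <- lapply(seq_along(x$states), function(i) {
    s <- x$states[[i]]
    data.frame(
      t = s$t,
      variable = c("bio", "mu",
                   paste0("comp_", names(s$composition)),
                   paste0("env_", names(s$environment))),
      value = c(s$bio, if (i > 1) x$mu[i - 1] else NA_real_,
                as.numeric(s$composition), as.numeric(s$environment)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot a dynamic-FBA trajectory
#' @param x a `dfba_trajectory`.
#' @param vars environment metabolites to draw alongside biomass.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dfba_trajectory <- function(x, vars = c("no3", "nh4", "pi", "sioh4"),
                                 ...) {
  t <- vapply(x$states, `[[`, 0, "t")
  bio <- vapply(x$states, `[[`, 0, "bio")
  env <- t(vapply(x$states, function(s) s$environment[vars], numeric(length(vars))))
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(t, bio, type = "l", xlab = "time (h)",
                 ylab = "biomass (g/L)", ...)
  graphics::matplot(t, env, type = "l", lty = 1, xlab = "time (h)",
                    ylab = "concentration (mM)", ...)
  graphics::legend("topright", legend = vars, col = seq_along(vars),
                   lty = 1, bty = "n")
  invisible(x)
}
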