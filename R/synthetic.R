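## Synthetic fixtures: a curated ~100-reaction mini-phototroph network
## spanning six compartments, chemostat photosynthesis-irradiance datasets,
## and a batch-culture nitrogen-starvation time series. Everything is
## generated in code, deterministically for a given seed.

## ---------------------------------------------------------------------
## reaction closure: given a skeleton stoichiometry whose C/N/P/S/Si books
## already balance, close O with water, then H and charge with protons and
## (optionally) a redox cofactor pair. Electron mismatches surface as an
## unsolvable charge residual, so a wrong skeleton cannot slip through.
close_reaction <- function(st, mets, h2o = NULL, h = NULL, redox = NULL,
                           tol = 1e-9) {
  met_formula <- stats::setNames(mets$formula, mets$id)
  met_charge <- stats::setNames(mets$charge, mets$id)
  total <- function(st) {
    tot <- stats::setNames(numeric(0), character(0))
    for (i in seq_along(st)) {
      tot <- formula_add(tot, parse_formula(met_formula[[names(st)[i]]]),
                         w = st[[i]])
    }
    list(f = tot, charge = sum(st * met_charge[names(st)]))
  }
  bal <- total(st)
  gx <- function(v, el) if (el %in% names(v)) v[[el]] else 0
  hard <- setdiff(names(bal$f), c("H", "O"))
  if (any(abs(bal$f[hard]) > tol)) {
    stop("skeleton imbalanced in ", paste(hard[abs(bal$f[hard]) > tol],
                                          collapse = ","))
  }
  add <- function(st, id, w) {
    if (abs(w) < tol) return(st)
    st[id] <- (if (id %in% names(st)) st[[id]] else 0) + w
    st[abs(st) > tol]
  }
  if (!is.null(redox)) {
    ## unknowns: a water, b protons, r redox extent (+r ox, -r rd);
    ## close O, H and charge simultaneously
    dox <- parse_formula(met_formula[[redox[["ox"]]]])
    drd <- parse_formula(met_formula[[redox[["rd"]]]])
    dO <- gx(dox, "O") - gx(drd, "O")
    dH <- gx(dox, "H") - gx(drd, "H")
    dC <- met_charge[[redox[["ox"]]]] - met_charge[[redox[["rd"]]]]
    M <- rbind(c(1, 0, dO),   # O
               c(2, 1, dH),   # H
               c(0, 1, dC))   # charge
    rhs <- -c(gx(bal$f, "O"), gx(bal$f, "H"), bal$charge)
    sol <- solve(M, rhs)
    st <- add(st, h2o, sol[1])
    st <- add(st, h, sol[2])
    st <- add(st, redox[["ox"]], sol[3])
    st <- add(st, redox[["rd"]], -sol[3])
  } else {
    if (!is.null(h2o)) {
      st <- add(st, h2o, -gx(bal$f, "O"))
      bal <- total(st)
    }
    if (!is.null(h)) st <- add(st, h, -gx(bal$f, "H"))
  }
  bal <- total(st)
  if (max(abs(c(bal$f, bal$charge))) > 1e-7) {
    stop("reaction cannot be closed: residual ",
         paste(names(bal$f), round(bal$f, 4), collapse = " "),
         " charge ", round(bal$charge, 4))
  }
  st
}

## metabolite catalog for the mini-phototroph: base id, formula, charge
toy_metabolite_table <- function(frustule_formula = "SiO2.5H") {
  base <- rbind(
    c("h2o", "H2O", 0), c("h", "H", 1), c("o2", "O2", 0),
    c("co2", "CO2", 0), c("hco3", "CHO3", -1),
    c("pi", "HO4P", -2), c("ppi", "HO7P2", -3),
    c("atp", "C10H12N5O13P3", -4), c("adp", "C10H12N5O10P2", -3),
    c("amp", "C10H12N5O7P", -2),
    c("nad", "C21H26N7O14P2", -1), c("nadh", "C21H27N7O14P2", -2),
    c("nadp", "C21H25N7O17P3", -3), c("nadph", "C21H26N7O17P3", -4),
    c("no3", "NO3", -1), c("no2", "NO2", -1), c("nh4", "H4N", 1),
    c("so4", "O4S", -2), c("so3", "O3S", -2), c("h2s", "H2S", 0),
    c("aps", "C10H12N5O10PS", -2),
    c("sioh4", "H4O4Si", 0), c("mg2", "Mg", 2),
    c("g3p", "C3H5O6P", -2), c("pg3", "C3H4O7P", -3),
    c("rb15bp", "C5H8O11P2", -4), c("2pglyc", "C2H2O6P", -3),
    c("glyclt", "C2H3O3", -1), c("glx", "C2HO3", -1),
    c("h2o2", "H2O2", 0), c("gly", "C2H5NO2", 0),
    c("glu__L", "C5H8NO4", -1), c("akg", "C5H4O5", -2),
    c("pyr", "C3H3O3", -1), c("etoh", "C2H6O", 0),
    c("for", "CHO2", -1), c("ac", "C2H3O2", -1),
    c("dmsp", "C5H10O2S", 0), c("dhps", "C3H7O5S", -1),
    c("pq", "C13H18O2", 0), c("pqh2", "C13H20O2", 0),
    c("pcox", "", 0), c("pcrd", "", -1),
    c("fdxox", "", 0), c("fdxrd", "", -1),
    c("trdox", "", 0), c("trdrd", "H2", 0),
    c("uq", "", 0), c("uqh2", "H2", 0),
    ## biomass component species
    ## the protein unit carries cysteine/methionine sulfur (~0.5% w/w)
    c("protein", "C5H7NO3S0.02", 0), c("faa", "C5H9NO4", 0),
    c("chryso", "C6H10O5", 0), c("lipid", "C39H70O10", 0),
    c("tag", "C55H98O6", 0), c("rna", "C10H12N5O7P", -2),
    c("dna", "C10H12N5O6P", -2), c("chitin", "C8H13NO5", 0),
    c("polyp", "O3P", -1), c("cofactor", "C21H26N7O14P2", -1),
    c("chla", "C55H72MgN4O5", 0), c("chlc", "C35H30MgN4O5", 0),
    c("fucox", "C42H58O6", 0), c("diadino", "C40H54O3", 0),
    c("bcar", "C40H56", 0),
    c("frus", frustule_formula, 0),
    c("biomass", "", 0)
  )
  data.frame(base = base[, 1], formula = base[, 2],
             charge = as.numeric(base[, 3]), stringsAsFactors = FALSE)
}

#' Default biomass composition of the mini-phototroph (g per gDW)
#' @param acclimation light-acclimation label; shifts protein/carbohydrate
#'   and pigment content the way light acclimation does in diatoms.
#' @return named numeric summing to 1.
#' @export
toy_biomass_composition <- function(acclimation = c("medium", "low", "high")) {
  acclimation <- match.arg(acclimation)
  base <- switch(acclimation,
    low = c(protein = 0.44, faa = 0.03, chryso = 0.10, lipid = 0.10,
            tag = 0.010, rna = 0.040, dna = 0.010, chitin = 0.015,
            polyp = 0.005, cofactor = 0.010, chla = 0.030, chlc = 0.007,
            fucox = 0.016, diadino = 0.002, bcar = 0.0012,
            dmsp = 0.012, dhps = 0.005),
    medium = c(protein = 0.35, faa = 0.03, chryso = 0.20, lipid = 0.12,
               tag = 0.030, rna = 0.050, dna = 0.010, chitin = 0.020,
               polyp = 0.005, cofactor = 0.010, chla = 0.015, chlc = 0.004,
               fucox = 0.008, diadino = 0.002, bcar = 0.001,
               dmsp = 0.010, dhps = 0.005),
    high = c(protein = 0.26, faa = 0.025, chryso = 0.32, lipid = 0.13,
             tag = 0.050, rna = 0.045, dna = 0.010, chitin = 0.020,
             polyp = 0.005, cofactor = 0.010, chla = 0.008, chlc = 0.002,
             fucox = 0.004, diadino = 0.0045, bcar = 0.002,
             dmsp = 0.010, dhps = 0.005))
  c(base, frustule = 1 - sum(base))
}

## component -> precursor metabolite map of the mini-phototroph
toy_component_metabolites <- function() c(
  protein = "protein_c", faa = "faa_c", chryso = "chryso_c",
  lipid = "lipid_c", tag = "tag_c", rna = "rna_c", dna = "dna_c",
  chitin = "chitin_c", polyp = "polyp_c", cofactor = "cofactor_c",
  chla = "chla_h", chlc = "chlc_h", fucox = "fucox_h",
  diadino = "diadino_h", bcar = "bcar_h", dmsp = "dmsp_c",
  dhps = "dhps_c", frustule = "frus_e")

#' Component elemental formulas of the mini-phototroph
#' @param condensation_fraction silica condensation fraction for the
#'   frustule unit formula.
#' @return named character vector of formulas.
#' @export
toy_component_formulas <- function(condensation_fraction = 0.75) {
  tab <- toy_metabolite_table(
    frustule_formula = frustule_reaction(condensation_fraction)$unit_formula)
  comp <- toy_component_metabolites()
  base <- sub("_[a-z]$", "", comp)
  stats::setNames(tab$formula[match(base, tab$base)], names(comp))
}

#' Build the synthetic mini-phototroph metabolic model
#'
#' A curated ~100-reaction, six-compartment network with the canonical
#' diatom machinery: per-waveband photon exchanges feeding PSII/PSI charge
#' separation via fucoxanthin chlorophyll a/c antenna transfer, cytochrome
#' b6/f, cyclic electron flow, plastid ATP synthase, RuBisCO carboxylase
#' and oxygenase with a lumped Calvin route to G3P, the truncated
#' photorespiratory glycolate route through peroxisomal glycolate oxidase,
#' Mehler and plastid terminal oxidases, mitochondrial NADH dehydrogenase,
#' alternative oxidase, cytochrome c oxidase and lumped TCA dehydrogenases,
#' nitrate/nitrite reduction with GS-GOGAT, sulfate assimilation through
#' APS to sulfide plus a sulfotransferase route to DHPS and a DMSP route,
#' silica frustule condensation, fermentative by-products (ethanol,
#' formate, acetate), an ATP maintenance reaction, and a parameterized
#' biomass objective. All non-boundary reactions are mass- and
#' charge-balanced; the network contains no energy-generating cycles.
#'
#' @param light_intensity incident irradiance (umol photons m^-2 s^-1)
#'   used for the default photon bounds.
#' @param acclimation pigment/biomass acclimation label.
#' @param gam growth-associated maintenance embedded in the biomass
#'   reaction (mmol ATP gDW^-1).
#' @param condensation_fraction silica condensation fraction q.
#' @param ngam non-growth ATP maintenance set as the ATPM lower bound
#'   (mmol gDW^-1 h^-1).
#' @return a [metabolic_model()].
#' @export
make_toy_phototroph_model <- function(light_intensity = 60,
                                      acclimation = "medium",
                                      gam = 30,
                                      condensation_fraction = 0.75,
                                      ngam = 0) {
  fr <- frustule_reaction(condensation_fraction)
  tab <- toy_metabolite_table(frustule_formula = fr$unit_formula)
  tf <- function(base) tab$formula[tab$base == base]
  tc <- function(base) tab$charge[tab$base == base]

  ## instantiate compartment-specific metabolites
  want <- list(
    e = c("no3", "nh4", "so4", "pi", "sioh4", "co2", "hco3", "o2", "h2o",
          "h", "mg2", "dmsp", "dhps", "etoh", "for", "ac", "glyclt",
          "glu__L", "gly", "frus"),
    c = c("h2o", "h", "o2", "co2", "hco3", "pi", "atp", "adp", "amp",
          "nad", "nadh", "no3", "no2", "nh4", "so4", "sioh4", "mg2",
          "g3p", "pyr", "etoh", "for", "ac", "glu__L", "gly", "dmsp",
          "dhps", "glyclt", "h2s",
          "protein", "faa", "chryso", "lipid", "tag", "rna", "dna",
          "chitin", "polyp", "cofactor", "biomass"),
    h = c("h2o", "h", "o2", "co2", "pi", "ppi", "atp", "adp", "amp",
          "nadp", "nadph", "fdxox", "fdxrd", "trdox", "trdrd", "pq",
          "pqh2", "pcox", "pcrd", "rb15bp", "pg3", "g3p", "2pglyc",
          "glyclt", "no2", "nh4", "akg", "glu__L", "so4", "so3", "h2s",
          "aps", "mg2", "chla", "chlc", "fucox", "diadino", "bcar",
          "dmsp", "dhps", "lipid", "tag"),
    u = c("h"),
    m = c("h2o", "h", "o2", "co2", "pi", "atp", "adp", "nad", "nadh",
          "uq", "uqh2", "pyr"),
    x = c("h2o", "h", "o2", "h2o2", "glyclt", "glx", "gly", "nh4",
          "nad", "nadh")
  )
  mets <- list()
  for (cp in names(want)) {
    for (b in want[[cp]]) {
      mets[[paste0(b, "_", cp)]] <- metabolite(
        paste0(b, "_", cp), name = b, formula = tf(b), charge = tc(b),
        compartment = cp)
    }
  }
  mets[["ex_chla_u"]] <- metabolite("ex_chla_u",
                                    name = "excited chlorophyll a",
                                    formula = "", charge = 0,
                                    compartment = "u")
  metdf <- do.call(rbind, lapply(mets, function(m) {
    data.frame(id = m$id, formula = m$formula, charge = m$charge,
               stringsAsFactors = FALSE)
  }))

  RX <- list()
  add <- function(id, st, lb = 0, ub = 1000, sub = NA_character_,
                  close = NULL) {
    st <- st[abs(st) > 1e-12]
    if (!is.null(close)) {
      st <- close_reaction(st, metdf, h2o = close$h2o, h = close$h,
                           redox = close$redox)
    }
    RX[[id]] <<- reaction(id, st, lower_bound = lb, upper_bound = ub,
                          subsystem = sub)
  }
  ch <- list(h2o = "h2o_h", h = "h_h")
  chN <- list(h2o = "h2o_h", h = "h_h",
              redox = c(ox = "nadp_h", rd = "nadph_h"))
  chF <- list(h2o = "h2o_h", h = "h_h",
              redox = c(ox = "fdxox_h", rd = "fdxrd_h"))
  chT <- list(h2o = "h2o_h", h = "h_h",
              redox = c(ox = "trdox_h", rd = "trdrd_h"))
  cc <- list(h2o = "h2o_c", h = "h_c")
  ccN <- list(h2o = "h2o_c", h = "h_c",
              redox = c(ox = "nad_c", rd = "nadh_c"))
  cm <- list(h2o = "h2o_m", h = "h_m")

  ## --- photosynthetic electron transport (thylakoid) ---
  ## units: charge-separation fluxes count single electrons (one exciton
  ## per electron); quinol-level reactions (CBFC2, CEF, PTOX) count
  ## 2-electron quinol units -- the convention the electron-flow
  ## expressions assume
  add("PSIICS", c(ex_chla_u = -1, h2o_h = -0.5, pq_h = -0.5, h_h = -1,
                  o2_h = 0.25, pqh2_h = 0.5, h_u = 1),
      sub = "Photosynthesis")
  add("CBFC2", c(pqh2_h = -1, pcox_h = -2, h_h = -2,
                 pq_h = 1, pcrd_h = 2, h_u = 4), sub = "Photosynthesis")
  add("PSICS", c(ex_chla_u = -1, pcrd_h = -1, fdxox_h = -1,
                 pcox_h = 1, fdxrd_h = 1), sub = "Photosynthesis")
  add("CEF", c(fdxrd_h = -2, pq_h = -1, h_h = -2, fdxox_h = 2, pqh2_h = 1),
      sub = "Photosynthesis")
  add("FNR_h", c(fdxrd_h = -2, nadp_h = -1, h_h = -1,
                 fdxox_h = 2, nadph_h = 1), sub = "Photosynthesis")
  add("ATPS_h", c(adp_h = -1, pi_h = -1, h_u = -4,
                  atp_h = 1, h2o_h = 1, h_h = 3), sub = "Photosynthesis")
  add("MEHLER_h", c(o2_h = -1, fdxrd_h = -4, h_h = -4,
                    h2o_h = 2, fdxox_h = 4), sub = "Alternative electron flow")
  add("PTOX_h", c(pqh2_h = -1, o2_h = -0.5, pq_h = 1, h2o_h = 1),
      sub = "Alternative electron flow")
  add("TRDR_h", c(nadph_h = -1, h_h = -1, trdox_h = -1,
                  nadp_h = 1, trdrd_h = 1), sub = "Redox carriers")

  ## --- Calvin cycle and photorespiration ---
  add("RUBISC_h", c(rb15bp_h = -1, co2_h = -1, h2o_h = -1,
                    pg3_h = 2, h_h = 2), sub = "Calvin cycle")
  add("RUBISO_h", c(rb15bp_h = -1, o2_h = -1, pg3_h = 1, `2pglyc_h` = 1,
                    h_h = 2), sub = "Photorespiration")
  add("PGR_h", c(pg3_h = -1, atp_h = -1, nadph_h = -1, h_h = -1,
                 g3p_h = 1, adp_h = 1, nadp_h = 1, pi_h = 1),
      sub = "Calvin cycle")
  add("RBPR_h", c(g3p_h = -5, atp_h = -3, h2o_h = -2,
                  rb15bp_h = 3, adp_h = 3, pi_h = 2, h_h = 3),
      sub = "Calvin cycle")
  add("PGP_h", c(`2pglyc_h` = -1, h2o_h = -1, glyclt_h = 1, pi_h = 1),
      sub = "Photorespiration")
  add("GLYCTO_x", c(glyclt_x = -1, o2_x = -1, glx_x = 1, h2o2_x = 1),
      sub = "Photorespiration")
  add("CAT_x", c(h2o2_x = -2, h2o_x = 2, o2_x = 1), sub = "Photorespiration")
  add("GLYS_x", c(glx_x = -1, nh4_x = -1, nadh_x = -1, h_x = -1,
                  gly_x = 1, nad_x = 1, h2o_x = 1), sub = "Photorespiration")

  ## --- plastid anabolism ---
  ## reversible: the reverse direction returns carbon skeletons from
  ## 2-oxoglutarate released by amino-acid catabolism (remobilization)
  add("AKGS_h", c(g3p_h = -2, akg_h = 1, co2_h = 1, pi_h = 2),
      lb = -1000, sub = "Central carbon", close = chN)
  add("GOGAT_h", c(akg_h = -1, nh4_h = -1, atp_h = -1,
                   glu__L_h = 1, adp_h = 1, pi_h = 1),
      sub = "N assimilation", close = chF)
  add("NiR_h", c(no2_h = -1, nh4_h = 1), sub = "N assimilation", close = chF)
  ## catabolic deamination: releases ammonium from remobilized amino acids
  add("GDH_h", c(glu__L_h = -1, akg_h = 1, nh4_h = 1),
      sub = "N assimilation", close = chN)
  add("SAT_h", c(so4_h = -1, atp_h = -1, aps_h = 1, ppi_h = 1),
      sub = "S assimilation", close = ch)
  add("PPA_h", c(ppi_h = -1, h2o_h = -1, pi_h = 2, h_h = 1),
      sub = "S assimilation")
  add("APSR_h", c(aps_h = -1, so3_h = 1, amp_h = 1),
      sub = "S assimilation", close = chT)
  add("SO3R_h", c(so3_h = -1, h2s_h = 1), sub = "S assimilation", close = chF)
  add("ADK_h", c(amp_h = -1, atp_h = -1, adp_h = 2), lb = -1000,
      sub = "Energy")
  add("DMSPS_h", c(g3p_h = -2, h2s_h = -1, dmsp_h = 1, co2_h = 1, pi_h = 2),
      sub = "S assimilation", close = chN)
  add("SLFT_h", c(g3p_h = -1, so3_h = -1, dhps_h = 1, pi_h = 1),
      sub = "S assimilation", close = chN)
  pig_syn <- list(
    CHLAS_h = list(p = "chla_h", g3p = 55 / 3, atp = 5, nh4 = 4, mg = 1),
    CHLCS_h = list(p = "chlc_h", g3p = 35 / 3, atp = 5, nh4 = 4, mg = 1),
    FXS_h = list(p = "fucox_h", g3p = 14, atp = 3, nh4 = 0, mg = 0),
    DDXS_h = list(p = "diadino_h", g3p = 40 / 3, atp = 3, nh4 = 0, mg = 0),
    BCARS_h = list(p = "bcar_h", g3p = 40 / 3, atp = 3, nh4 = 0, mg = 0))
  for (id in names(pig_syn)) {
    z <- pig_syn[[id]]
    st <- c(-z$g3p, -z$atp, -z$nh4, -z$mg, 1, z$atp, z$g3p + z$atp)
    names(st) <- c("g3p_h", "atp_h", "nh4_h", "mg2_h", z$p, "adp_h", "pi_h")
    add(id, st, sub = "Pigment biosynthesis", close = chN)
  }
  add("LIPS_h", c(g3p_h = -13, atp_h = -3, lipid_h = 1, adp_h = 3, pi_h = 16),
      sub = "Lipid biosynthesis", close = chN)
  add("TAGS_h", c(g3p_h = -55 / 3, atp_h = -3, tag_h = 1, adp_h = 3,
                  pi_h = 55 / 3 + 3), sub = "Lipid biosynthesis", close = chN)

  ## --- cytosolic metabolism ---
  add("GLYC_c", c(g3p_c = -1, adp_c = -2, pi_c = -1, pyr_c = 1, atp_c = 2),
      sub = "Glycolysis", close = ccN)
  add("PROTS_c", c(glu__L_c = -1, h2s_c = -0.02, atp_c = -4, protein_c = 1,
                   adp_c = 4, pi_c = 4),
      sub = "Biomass component synthesis", close = ccN)
  add("PROTD_c", c(protein_c = -1, glu__L_c = 1, h2s_c = 0.02),
      sub = "Remobilization", close = ccN)
  add("FAAS_c", c(glu__L_c = -1, h_c = -1, faa_c = 1), lb = -1000,
      sub = "Biomass component synthesis")
  add("CHRSYS_c", c(g3p_c = -2, atp_c = -1, chryso_c = 1, adp_c = 1,
                    pi_c = 3), sub = "Biomass component synthesis",
      close = ccN)
  add("CHRDEG_c", c(chryso_c = -1, atp_c = -2, g3p_c = 2, adp_c = 2),
      sub = "Remobilization", close = ccN)
  add("RNAS_c", c(g3p_c = -10 / 3, nh4_c = -5, atp_c = -6, rna_c = 1,
                  adp_c = 6, pi_c = 10 / 3 + 5),
      sub = "Biomass component synthesis", close = ccN)
  add("RNAD_c", c(rna_c = -1, pi_c = -7 / 3, g3p_c = 10 / 3, nh4_c = 5),
      sub = "Remobilization", close = ccN)
  add("DNAS_c", c(rna_c = -1, dna_c = 1),
      sub = "Biomass component synthesis", close = ccN)
  add("CHITS_c", c(g3p_c = -8 / 3, nh4_c = -1, atp_c = -2, chitin_c = 1,
                   adp_c = 2, pi_c = 8 / 3 + 2),
      sub = "Biomass component synthesis", close = ccN)
  add("CHITD_c", c(chitin_c = -1, pi_c = -8 / 3, g3p_c = 8 / 3, nh4_c = 1),
      sub = "Remobilization", close = ccN)
  add("POLYPS_c", c(atp_c = -1, adp_c = 1, polyp_c = 1),
      sub = "Biomass component synthesis")
  add("POLYPD_c", c(polyp_c = -1, h2o_c = -1, pi_c = 1, h_c = 1),
      sub = "Remobilization")
  add("NADS_c", c(g3p_c = -7, nh4_c = -7, atp_c = -4, nad_c = 1, adp_c = 4,
                  pi_c = 9), sub = "Cofactor biosynthesis",
      close = list(h2o = "h2o_c", h = "h_c",
                   redox = c(ox = "o2_c", rd = "h2o_c")))
  add("COFS_c", c(nad_c = -1, cofactor_c = 1), sub = "Cofactor biosynthesis")
  add("NR_c", c(no3_c = -1, nadh_c = -1, h_c = -1, no2_c = 1, nad_c = 1,
                h2o_c = 1), sub = "N assimilation")
  add("ETOHS_c", c(pyr_c = -1, nadh_c = -1, h_c = -2, etoh_c = 1, co2_c = 1,
                   nad_c = 1), sub = "Fermentation")
  add("ETOHD_c", c(etoh_c = -1, ac_c = 1), sub = "Fermentation", close = ccN)
  add("PFL_c", c(pyr_c = -1, h2o_c = -1, for_c = 1, ac_c = 1, h_c = 1),
      sub = "Fermentation")
  add("FORD_c", c(for_c = -1, co2_c = 1), sub = "Fermentation", close = ccN)
  add("ACS_c", c(ac_c = -1, co2_c = -1, atp_c = -2, pyr_c = 1, adp_c = 2,
                 pi_c = 2), sub = "Central carbon", close = ccN)
  add("GLYCONV_c", c(gly_c = -2.5, glu__L_c = 1, nh4_c = 1.5),
      sub = "Central carbon", close = ccN)
  add("CA_c", c(hco3_c = -1, h_c = -1, co2_c = 1, h2o_c = 1), lb = -1000,
      sub = "Carbon concentrating")
  add("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      lb = ngam, sub = "Maintenance")

  ## --- mitochondrion ---
  add("TCADH_m", c(pyr_m = -1, nad_m = -4, adp_m = -1, pi_m = -1, uq_m = -1,
                   co2_m = 3, nadh_m = 4, atp_m = 1, uqh2_m = 1),
      sub = "TCA cycle", close = cm)
  add("NADHOR_m", c(nadh_m = -1, h_m = -1, uq_m = -1, nad_m = 1, uqh2_m = 1),
      sub = "Respiration")
  add("CYOO_m", c(uqh2_m = -1, o2_m = -0.5, adp_m = -2.5, pi_m = -2.5,
                  h_m = -2.5, uq_m = 1, atp_m = 2.5, h2o_m = 3.5),
      sub = "Respiration")
  add("AOX_m", c(uqh2_m = -1, o2_m = -0.5, uq_m = 1, h2o_m = 1),
      sub = "Respiration")

  ## --- frustule ---
  RX[["FRUST"]] <- fr$reaction
  RX[["FRUST"]]$subsystem <- "Frustule"

  ## --- transporters ---
  tr <- function(id, from, to, lb = -1000, sub = "Transport") {
    add(id, stats::setNames(c(-1, 1), c(from, to)), lb = lb, sub = sub)
  }
  tr("CO2t_h", "co2_c", "co2_h"); tr("O2t_h", "o2_c", "o2_h")
  tr("H2Ot_h", "h2o_c", "h2o_h"); tr("PIt_h", "pi_c", "pi_h")
  tr("NO2t_h", "no2_c", "no2_h"); tr("NH4t_h", "nh4_h", "nh4_c")
  tr("SO4t_h", "so4_c", "so4_h"); tr("GLUt_h", "glu__L_h", "glu__L_c")
  tr("G3Pt_h", "g3p_h", "g3p_c"); tr("GLYCLTt_h", "glyclt_h", "glyclt_c")
  tr("H2St_h", "h2s_h", "h2s_c"); tr("DMSPt_h", "dmsp_h", "dmsp_c")
  tr("DHPSt_h", "dhps_h", "dhps_c"); tr("MG2t_h", "mg2_c", "mg2_h")
  tr("LIPt_h", "lipid_h", "lipid_c"); tr("TAGt_h", "tag_h", "tag_c")
  add("AAC_h", c(atp_h = -1, adp_c = -1, atp_c = 1, adp_h = 1), lb = -1000,
      sub = "Transport")
  tr("PYRt_m", "pyr_c", "pyr_m"); tr("O2t_m", "o2_c", "o2_m")
  tr("CO2t_m", "co2_c", "co2_m"); tr("H2Ot_m", "h2o_c", "h2o_m")
  tr("PIt_m", "pi_c", "pi_m")
  add("AAC_m", c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1), lb = -1000,
      sub = "Transport")
  add("SHUTTLE_m", c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1),
      lb = -1000, sub = "Transport")
  tr("GLYCLTt_x", "glyclt_c", "glyclt_x"); tr("O2t_x", "o2_c", "o2_x")
  tr("H2Ot_x", "h2o_c", "h2o_x"); tr("GLYt_x", "gly_x", "gly_c")
  tr("NH4t_x", "nh4_c", "nh4_x")
  add("SHUTTLE_x", c(nadh_c = -1, nad_x = -1, nad_c = 1, nadh_x = 1),
      lb = -1000, sub = "Transport")
  ## plasma membrane
  add("NO3t", c(no3_e = -1, h_e = -1, no3_c = 1, h_c = 1), lb = 0,
      sub = "Transport")
  tr("NH4t", "nh4_e", "nh4_c"); tr("SO4t", "so4_e", "so4_c")
  tr("PIt", "pi_e", "pi_c"); tr("SIT", "sioh4_e", "sioh4_c")
  tr("CO2t", "co2_e", "co2_c"); tr("HCO3t", "hco3_e", "hco3_c")
  tr("O2t", "o2_e", "o2_c"); tr("H2Ot", "h2o_e", "h2o_c")
  tr("Ht", "h_e", "h_c"); tr("MG2t", "mg2_e", "mg2_c")
  tr("ETOHt", "etoh_c", "etoh_e"); tr("FORt", "for_c", "for_e")
  tr("ACt", "ac_c", "ac_e"); tr("GLYCLTt_e", "glyclt_c", "glyclt_e")
  tr("DMSPt_e", "dmsp_c", "dmsp_e"); tr("DHPSt_e", "dhps_c", "dhps_e")
  tr("GLUt_e", "glu__L_c", "glu__L_e"); tr("GLYt_e", "gly_c", "gly_e")

  ## --- exchanges ---
  exch_lb <- c(no3 = -10, nh4 = 0, so4 = -10, pi = -10, sioh4 = -10,
               co2 = -10, hco3 = -10, o2 = -1000, h2o = -1000, h = -1000,
               mg2 = -10, dmsp = 0, dhps = 0, etoh = 0, `for` = 0, ac = 0,
               glyclt = 0, glu__L = 0, gly = 0, frus = 0)
  for (b in names(exch_lb)) {
    add(paste0("EX_", b, "_e"), stats::setNames(-1, paste0(b, "_e")),
        lb = exch_lb[[b]], ub = 1000, sub = "Exchange")
  }

  ## --- chlorophyll a degradation demand (remobilization outlet) ---
  add("DM_chla_h", c(chla_h = -1), lb = 0, ub = 0, sub = "Remobilization")

  ## --- sink reactions, closed by default ---
  ## negative flux supplies the species: used for transient carbon pools
  ## (chrysolaminarin / G3P) and for biomass-component remobilization
  for (sk in c("chryso_c", "g3p_c", "protein_c", "faa_c", "rna_c", "tag_c",
               "chitin_c", "polyp_c", "chla_h")) {
    add(paste0("SK_", sk), stats::setNames(-1, sk), lb = 0, ub = 0,
        sub = "Sink")
  }

  ## --- biomass ---
  comp <- toy_biomass_composition(acclimation)
  bof <- build_biomass_objective(
    biomass_composition(comp, basis = "gDW"),
    toy_component_formulas(condensation_fraction),
    toy_component_metabolites(), gam = gam)
  RX[[bof$id]] <- bof
  add("DM_biomass_c", c(biomass_c = -1), sub = "Biomass")

  ## gene associations: deterministic synthetic loci
  k <- 0L
  for (id in names(RX)) {
    if (length(RX[[id]]$stoichiometry) > 1L &&
        !id %in% c("BIOMASS", "DM_biomass_c", "ATPM")) {
      k <- k + 1L
      RX[[id]]$gene_association <- if (k %% 7 == 0) {
        sprintf("(tp%04d and tp%04d)", k, k + 500L)
      } else if (k %% 5 == 0) {
        sprintf("(tp%04d or tp%04d)", k, k + 500L)
      } else sprintf("tp%04d", k)
    }
  }

  model <- metabolic_model(
    mets, unname(RX),
    objective = c(DM_biomass_c = 1),
    compartments = c(c = "cytosol", e = "extracellular", h = "plastid",
                     m = "mitochondrion", u = "thylakoid lumen",
                     x = "peroxisome"),
    id = "mini_phototroph")

  ## mechanistic light layer (antenna, de-excitation, D1 accounting)
  build_light_reactions(model, default_pigment_profile(acclimation),
                        default_light_source(),
                        light_condition(light_intensity))
}

#' Synthetic chemostat photosynthesis-irradiance dataset
#'
#' Emulates steady-state chemostats at three growth irradiances: gross
#' photosynthesis sampled from a saturating-exponential (Platt) curve and
#' net photosynthesis from a hyperbolic-tangent (Chalker) curve with
#' multiplicative Gaussian noise, plus per-condition biomass compositions
#' (protein and pigments fall with light, carbohydrates rise; the frustule
#' is heaviest in the slow-growing low-light cells), dilution rates, cell
#' densities, and media reservoir concentrations.
#'
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @param light_levels growth irradiances (umol photons m^-2 s^-1).
#' @param irradiances measurement irradiances of the P-I curves.
#' @param noise_sd multiplicative noise standard deviation (0 = noiseless).
#' @param replicates P-I replicates per irradiance.
#' @return list: `pi_curves` (condition, I, gpp, npp, replicate),
#'   `true_params` (generating Platt/Chalker parameters), `compositions`
#'   (condition, component, pg_cell), `cells` (condition, dilution_rate_h,
#'   cells_per_L), `reservoir_mM` (named media concentrations).
#' @export
make_chemostat_dataset <- function(seed = 1,
                                   light_levels = c(5, 60, 200),
                                   irradiances = c(2, 5, 10, 25, 50, 100,
                                                   200, 400, 800),
                                   noise_sd = 0.05, replicates = 3) {
  stopifnot(length(light_levels) == 3L)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  pars <- data.frame(
    condition = light_levels,
    Ps = c(1.5, 4.0, 7.0), alpha = c(0.12, 0.09, 0.06),
    ## dark respiration at 15-25% of Ps puts the compensation irradiance
    ## at ~2 (low) to ~30 (high light) umol photons m^-2 s^-1
    Ik = c(12.5, 44, 117), DR = c(-0.25, -1.0, -1.6))
  cur <- do.call(rbind, lapply(seq_len(3), function(i) {
    p <- pars[i, ]
    do.call(rbind, lapply(seq_len(replicates), function(rep) {
      gpp <- p$Ps * (1 - exp(-p$alpha * irradiances / p$Ps))
      npp <- p$Ps * tanh(irradiances / p$Ik) + p$DR
      data.frame(condition = p$condition, I = irradiances,
                 gpp = gpp * (1 + stats::rnorm(length(gpp), 0, noise_sd)),
                 npp = npp * (1 + stats::rnorm(length(npp), 0, noise_sd)),
                 replicate = rep)
    }))
  }))

  comp_pg <- list(
    ## per-cell masses (pg/cell); dry weights 22.4 / 16.6 / 17.8, frustule
    ## as the residual between dry weight and the measured components
    `5` = c(protein = 10.5, chryso = 2.65, lipid = 1.6, tag = 0.2,
            rna = 0.45, dna = 0.15, faa = 0.25, chitin = 0.2, polyp = 0.05,
            cofactor = 0.05, pigments = 0.9, dmsp = 0.15, dhps = 0.05),
    `60` = c(protein = 4.3, chryso = 6.85, lipid = 1.8, tag = 0.3,
             rna = 0.5, dna = 0.15, faa = 0.25, chitin = 0.2, polyp = 0.05,
             cofactor = 0.05, pigments = 0.35, dmsp = 0.15, dhps = 0.05),
    `200` = c(protein = 3.3, chryso = 9.6, lipid = 2.0, tag = 0.5,
              rna = 0.5, dna = 0.15, faa = 0.25, chitin = 0.2, polyp = 0.05,
              cofactor = 0.05, pigments = 0.3, dmsp = 0.15, dhps = 0.05))
  dw <- c(`5` = 22.4, `60` = 16.6, `200` = 17.8)
  compositions <- do.call(rbind, lapply(seq_along(light_levels), function(i) {
    key <- as.character(c(5, 60, 200)[i])
    m <- comp_pg[[key]]
    m <- c(m, frustule = unname(dw[key] - sum(m)))
    data.frame(condition = light_levels[i], component = names(m),
               pg_cell = as.numeric(m), stringsAsFactors = FALSE)
  }))

  cells <- data.frame(condition = light_levels,
                      dilution_rate_h = c(0.012, 0.042, 0.058),
                      cells_per_L = c(8e8, 6e8, 5e8))
  list(pi_curves = cur, true_params = pars, compositions = compositions,
       cells = cells,
       reservoir_mM = c(no3 = 0.25, pi = 0.050, sioh4 = 0.106, so4 = 28.8))
}

#' Synthetic batch-culture nitrogen-starvation time series
#'
#' Emulates a ten-day batch experiment sampled on days 0, 1, 3, 7 and 10
#' (mid-exponential, late-exponential 1 and 2, early and mid stationary):
#' per-cell biomass component targets that shift from protein toward
#' carbohydrate and lipid as nitrogen runs out, rising cell counts that
#' plateau, declining chlorophyll, an FRRf-style PSII flux bound series
#' (per mg chl a, with 95% confidence bounds), light-period fold-changes
#' for the diel storage compounds, and the initial environment: low
#' nitrate (tens of uM) against seawater-level sulfate (tens of mM).
#'
#' @param seed integer seed.
#' @param noise_sd relative jitter applied to the target compositions.
#' @return list of class `"batch_timeseries"`: `days`, `targets` (day,
#'   component, pg_cell), `cells_per_L`, `phases`, `fold_change`,
#'   `dark_excluded`, `psii` (day, center, lb, ub in mmol O2 per mg chl a
#'   per h), `environment_mM`, `initial_biomass_gL`.
#' @export
make_batch_timeseries <- function(seed = 1, noise_sd = 0.02) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  days <- c(0, 1, 3, 7, 10)
  base <- list(
    protein = c(4.5, 4.5, 2.3, 1.6, 1.3),
    faa     = c(0.30, 0.28, 0.20, 0.16, 0.15),
    chryso  = c(1.50, 2.20, 3.60, 5.20, 6.00),
    lipid   = c(1.80, 1.85, 1.95, 2.10, 2.20),
    tag     = c(0.20, 0.40, 1.00, 2.00, 2.50),
    rna     = c(0.50, 0.46, 0.36, 0.28, 0.25),
    dna     = c(0.15, 0.16, 0.20, 0.26, 0.30),
    chitin  = c(0.20, 0.20, 0.20, 0.20, 0.20),
    polyp   = c(0.05, 0.07, 0.12, 0.22, 0.30),
    cofactor = c(0.05, 0.05, 0.05, 0.05, 0.05),
    chla    = c(0.30, 0.28, 0.20, 0.13, 0.10),
    chlc    = c(0.08, 0.075, 0.055, 0.035, 0.027),
    fucox   = c(0.16, 0.15, 0.11, 0.07, 0.054),
    diadino = c(0.04, 0.04, 0.043, 0.048, 0.05),
    bcar    = c(0.02, 0.02, 0.021, 0.023, 0.024),
    ## osmolytes dilute during fast exponential division, then
    ## accumulate under N starvation (DMSP replacing N-rich osmolytes)
    dmsp    = c(0.10, 0.06, 0.18, 0.30, 0.38),
    dhps    = c(0.05, 0.03, 0.07, 0.09, 0.10),
    frustule = c(1.00, 1.02, 1.08, 1.16, 1.20))
  targets <- do.call(rbind, lapply(names(base), function(k) {
    v <- base[[k]] * (1 + stats::rnorm(length(days), 0, noise_sd))
    data.frame(day = days, component = k, pg_cell = pmax(v, 0),
               stringsAsFactors = FALSE)
  }))
  ## cell counts rise then plateau: early division is fast enough to
  ## exhaust the nitrate pool between days 1 and 3, and the plateau keeps
  ## the culture's total nitrogen demand within the initial nitrate +
  ## biomass N budget
  cells <- c(1.5e9, 2.4e9, 3.0e9, 3.2e9, 3.2e9)  # cells per litre
  psii_center <- c(0.18, 0.17, 0.17, 0.17, 0.25) *
    (1 + stats::rnorm(5, 0, noise_sd))
  psii <- data.frame(day = days, center = psii_center,
                     lb = psii_center * 0.85, ub = psii_center * 1.15)
  dw0 <- sum(vapply(base, `[[`, 0, 1))   # pg/cell on day 0
  structure(list(
    days = days, targets = targets, cells_per_L = cells,
    phases = c("mid_exponential", "late_exponential_1", "late_exponential_2",
               "early_stationary", "mid_stationary"),
    fold_change = c(chryso = 1.5, tag = 1.5),
    dark_excluded = c("chla", "chlc", "fucox", "diadino", "bcar",
                      "chryso", "tag"),
    psii = psii,
    environment_mM = c(no3 = 0.020, nh4 = 0.0005, pi = 0.0199,
                       sioh4 = 0.053, so4 = 28, mg2 = 50,
                       co2 = 0.0133, hco3 = 1.78, o2 = 0.21),
    initial_biomass_gL = cells[1] * dw0 * 1e-12
  ), class = "batch_timeseries")
}

## save/restore RNG around seeded generation, so fixtures do not disturb
## the caller's RNG stream
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}
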