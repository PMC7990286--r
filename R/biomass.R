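## Biomass objective construction, silica frustule chemistry, elemental
## formulas of biomass, degree of reduction, and photosynthetic quotients.

#' Biomass composition container
#'
#' @param masses named numeric, component -> mass. Components typically
#'   cover DNA, RNA, protein, free amino acids, pigments, carbohydrates,
#'   lipid classes, triacylglycerides, chitin, chrysolaminarin, osmolytes,
#'   frustule, polyphosphate and a soluble cofactor pool.
#' @param basis `"gDW"` (g per g dry weight; must sum to 1 within 0.01) or
#'   `"pg_cell"` (pg per cell).
#' @param cell_count optional cells per litre, for pg/cell to g/L conversion.
#' @return object of class `"biomass_composition"`.
#' @export
biomass_composition <- function(masses, basis = c("gDW", "pg_cell"),
                                cell_count = NULL) {
  basis <- match.arg(basis)
  if (any(masses < 0)) stop("component masses must be >= 0")
  if (basis == "gDW" && abs(sum(masses) - 1) > 0.01) {
    stop("gDW-basis composition must sum to 1 (got ", round(sum(masses), 4),
         ")")
  }
  structure(list(masses = masses, basis = basis, cell_count = cell_count),
            class = "biomass_composition")
}

#' Convert a per-cell composition to mass fractions of dry weight
#'
#' Divides by the composition's own total dry weight. When a measured total
#' dry weight is supplied and exceeds the component sum, the residual is
#' assigned to the frustule (the silica wall is the component typically not
#' measured directly but recovered as the difference between total dry
#' weight and the sum of the measured components).
#'
#' @param comp a [biomass_composition()] on a pg/cell basis.
#' @param total_dry_weight optional measured dry weight (pg/cell).
#' @param frustule_component name of the frustule component.
#' @return a gDW-basis [biomass_composition()].
#' @export
as_gdw_composition <- function(comp, total_dry_weight = NULL,
                               frustule_component = "frustule") {
  stopifnot(inherits(comp, "biomass_composition"))
  if (comp$basis == "gDW") return(comp)
  m <- comp$masses
  if (!is.null(total_dry_weight)) {
    resid <- total_dry_weight - sum(m[setdiff(names(m), frustule_component)])
    if (resid < -1e-9) {
      stop("components exceed the stated total dry weight")
    }
    m[frustule_component] <- resid
  }
  biomass_composition(m / sum(m), basis = "gDW",
                      cell_count = comp$cell_count)
}

#' Build a biomass objective reaction from a composition
#'
#' Converts mass fractions into millimolar contributions to 1 g dry weight:
#' `coefficient_i = 1000 * fraction_i / Mr_i` (mmol gDW^-1). The reaction
#' consumes the precursor metabolite of every component, optionally pays a
#' growth-associated ATP maintenance cost, and produces 1 g of a biomass
#' species. Mass closure (`sum coefficient_i * Mr_i / 1000 = 1`) is
#' guaranteed by construction and re-checked.
#'
#' @param comp a gDW-basis [biomass_composition()] (or pg/cell with
#'   `cell_count`/dry weight handled beforehand via [as_gdw_composition()]).
#' @param component_formulas named character or list: component ->
#'   elemental formula (used for Mr).
#' @param component_metabolites named character: component -> metabolite id
#'   consumed in the reaction. Defaults to the component names.
#' @param gam growth-associated maintenance (mmol ATP gDW^-1) embedded in
#'   the reaction as an ATP hydrolysis term.
#' @param biomass_metabolite id of the produced biomass species.
#' @param id reaction id.
#' @param atp_compartment suffix for the GAM ATP species (default cytosol).
#' @return an [reaction()] of class `"fba_reaction"`.
#' @export
build_biomass_objective <- function(comp, component_formulas,
                                    component_metabolites = NULL,
                                    gam = 0,
                                    biomass_metabolite = "biomass_c",
                                    id = "BIOMASS",
                                    atp_compartment = "c") {
  stopifnot(inherits(comp, "biomass_composition"))
  if (comp$basis != "gDW") {
    stop("composition must be on a gDW basis; see as_gdw_composition()")
  }
  fr <- comp$masses[comp$masses > 0]
  missing <- setdiff(names(fr), names(component_formulas))
  if (length(missing)) {
    stop("no elemental formula for component(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(component_metabolites)) {
    component_metabolites <- stats::setNames(names(fr), names(fr))
  }
  mr <- vapply(names(fr),
               function(k) molar_mass(component_formulas[[k]]), numeric(1))
  if (any(mr <= 0)) {
    stop("component(s) with non-positive molar mass: ",
         paste(names(fr)[mr <= 0], collapse = ", "))
  }
  coefs <- 1000 * fr / mr                     # mmol per gDW
  stopifnot(abs(sum(coefs * mr) / 1000 - 1) < 1e-6)
  st <- stats::setNames(-as.numeric(coefs),
                        unname(component_metabolites[names(fr)]))
  ## merge duplicated precursor metabolites
  st <- tapply(st, names(st), sum)
  st <- stats::setNames(as.numeric(st), names(st))
  if (gam > 0) {
    sfx <- paste0("_", atp_compartment)
    gamst <- stats::setNames(c(-gam, -gam, gam, gam, gam),
                             paste0(c("atp", "h2o", "adp", "pi", "h"), sfx))
    for (nm in names(gamst)) st[nm] <- (if (nm %in% names(st)) st[nm] else 0) + gamst[nm]
  }
  st[biomass_metabolite] <- 1
  r <- reaction(id, st, lower_bound = 0, upper_bound = 1000,
                name = "biomass objective", subsystem = "Biomass")
  attr(r, "gam") <- gam
  r
}

#' Silica frustule formation reaction
#'
#' Condensation of silicic acid into the frustule: full condensation of
#' Si(OH)4 to SiO2 releases 2 H2O per Si, so a condensation fraction `q`
#' (from NMR Q-speciation of the silica) releases `2q` H2O and leaves a
#' partially hydroxylated unit SiO(4-2q)H(4-4q).
#'
#' @param condensation_fraction q in `[0, 1]`.
#' @param sioh4 id of the silicic acid species consumed.
#' @param frustule id of the frustule unit species produced.
#' @param h2o id of the water species released.
#' @param id reaction id.
#' @return list with the [reaction()] (`reaction`), the frustule unit
#'   formula string (`unit_formula`) and its molar mass (`unit_mr`).
#' @export
frustule_reaction <- function(condensation_fraction, sioh4 = "sioh4_c",
                              frustule = "frus_e", h2o = "h2o_c",
                              id = "FRUST") {
  q <- condensation_fraction
  if (q < 0 || q > 1) stop("condensation fraction must lie in [0, 1]")
  unit <- c(Si = 1, O = 4 - 2 * q, H = 4 - 4 * q)
  unit <- unit[unit > 1e-12]
  st <- stats::setNames(c(-1, 1), c(sioh4, frustule))
  if (q > 0) st[h2o] <- 2 * q
  list(reaction = reaction(id, st, lower_bound = 0, upper_bound = 1000,
                           name = "frustule silica condensation",
                           subsystem = "Frustule"),
       unit_formula = format_formula(unit),
       unit_mr = molar_mass(unit))
}

#' Growth-rate dependent Si/C ratio
#'
#' Under light limitation the Si/C ratio follows a linear map of growth
#' rate (slow, light-limited divisions with non-saturable silicic acid
#' uptake give the heaviest frustules, so the slope is typically negative);
#' under N limitation a power law applies.
#'
#' @param growth_rate specific growth rate (h^-1), `>= 0`.
#' @param regime `"light_limited"` or `"N_limited"`.
#' @param params list: `slope` and `intercept` for the linear map,
#'   `a` and `k` for the power law `Si/C = a * mu^k`.
#' @return Si/C molar ratio.
#' @export
silica_per_cell <- function(growth_rate,
                            regime = c("light_limited", "N_limited"),
                            params = list(slope = -1.2, intercept = 0.13,
                                          a = 0.05, k = -0.4)) {
  stopifnot(growth_rate >= 0)
  regime <- match.arg(regime)
  if (regime == "light_limited") {
    params$intercept + params$slope * growth_rate
  } else {
    params$a * growth_rate^params$k
  }
}

#' Degree of reduction of a formula
#'
#' Electron equivalents per gram atom carbon:
#' `gamma = (4 C + 1 H - 2 O + n N + p P + s S) / C`, with the nitrogen
#' reference state setting `n = +5` (nitrate reference: assimilating N from
#' nitrate costs 8 electrons, which are credited to the biomass) or
#' `n = -3` (ammonia reference). Phosphorus and sulfur default to their
#' fully oxidized reference states (+5, +6).
#'
#' @param f formula string or named atom-count vector; must contain carbon.
#' @param n_reference `"nitrate"` or `"ammonia"`.
#' @param p_valence,s_valence valence contributions for P and S.
#' @return electron equivalents per gram atom C.
#' @export
#' @examples
#' degree_of_reduction("CH2O")   # 4, a carbohydrate
#' degree_of_reduction("CH4")    # 8
degree_of_reduction <- function(f, n_reference = c("nitrate", "ammonia"),
                                p_valence = 5, s_valence = 6) {
  n_reference <- match.arg(n_reference)
  counts <- if (is.character(f)) parse_formula(f) else f
  gx <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  if (gx("C") <= 0) stop("formula has no carbon")
  ncoef <- if (n_reference == "nitrate") 5 else -3
  (4 * gx("C") + gx("H") - 2 * gx("O") + ncoef * gx("N") +
     p_valence * gx("P") + s_valence * gx("S")) / gx("C")
}

#' Photosynthetic quotient of new biomass
#'
#' Balances the synthesis of one mole of biomass (formula `f`) from CO2,
#' H2O, and the nitrogen source (nitrate as HNO3 or ammonium as NH3; S as
#' H2SO4, P as H3PO4) and returns PQ = mol O2 evolved per mol CO2
#' assimilated. Because assimilating nitrate costs 8 electrons more per N
#' than ammonium, `PQ(nitrate) - PQ(ammonium) = 2 * N/C` exactly.
#'
#' @param f biomass elemental formula (string or counts); C required.
#' @param n_source `"nitrate"` or `"ammonium"`.
#' @return PQ (mol O2 per mol CO2).
#' @export
#' @examples
#' photosynthetic_quotient("CH2O", "ammonium")   # 1.0
#' photosynthetic_quotient("CH2", "ammonium")    # 1.5
photosynthetic_quotient <- function(f, n_source = c("nitrate", "ammonium")) {
  n_source <- match.arg(n_source)
  counts <- if (is.character(f)) parse_formula(f) else f
  gx <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  if (gx("C") <= 0) stop("formula has no carbon")
  ## CO2 + a H2O + n Nsrc + s H2SO4 + p H3PO4 -> biomass + PQ*C O2
  nsrc <- if (n_source == "nitrate") c(H = 1, N = 1, O = 3) else c(H = 3, N = 1)
  nN <- gx("N"); nS <- gx("S"); nP <- gx("P")
  ## hydrogen balance fixes water; oxygen balance fixes O2
  a <- (gx("H") - nN * nsrc[["H"]] - nS * 2 - nP * 3) / 2
  o_in <- 2 * gx("C") + a + nN * (if (n_source == "nitrate") 3 else 0) +
    nS * 4 + nP * 4
  o2 <- (o_in - gx("O")) / 2
  pq <- o2 / gx("C")
  if (pq < 0) stop("formula cannot be balanced: implied O2 evolution is negative")
  pq
}
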