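## Mechanistic light harvesting: per-20-nm photon absorption from pigment
## composition, excitation transfer to reaction-center chlorophyll a,
## de-excitation (heat/fluorescence) losses, and D1 photodamage accounting.

#' Wavelength bins of the photosynthetically active radiation range
#'
#' 15 half-open 20 nm bins spanning 400-700 nm, keyed by their lower edge.
#' @return integer vector of bin lower edges (nm).
#' @export
par_bins <- function() seq(400L, 680L, by = 20L)

## unit bridge: (umol photons m^-2 s^-1) * (m^2 gDW^-1)
##            = umol photons gDW^-1 s^-1 -> * 3600/1000 = mmol gDW^-1 h^-1
PHOTON_UNIT_BRIDGE <- 3.6

#' Spectral grid: light-source fractions and biomass-specific absorption
#'
#' @param source_fractions named numeric over [par_bins()]: fraction of the
#'   light source's photon flux in each bin; must sum to 1 over PAR.
#' @param absorption named numeric over [par_bins()]: biomass-specific
#'   absorption cross-section a (m^2 gDW^-1) per bin, all `>= 0`.
#' @return object of class `"spectral_grid"`.
#' @export
spectral_grid <- function(source_fractions, absorption) {
  bins <- as.character(par_bins())
  if (!all(bins %in% names(source_fractions)) ||
      !all(bins %in% names(absorption))) {
    stop("source_fractions and absorption must cover all 15 PAR bins (",
         "named by lower edge 400..680)")
  }
  r <- source_fractions[bins]; a <- absorption[bins]
  if (abs(sum(r) - 1) > 1e-9) stop("source fractions must sum to 1 over PAR")
  if (any(a < 0)) stop("absorption must be non-negative")
  structure(list(bins = par_bins(), r = r, a = a), class = "spectral_grid")
}

#' Light condition
#' @param intensity incident irradiance I (umol photons m^-2 s^-1), `>= 0`.
#' @param source label of the light-source spectrum.
#' @param acclimation acclimation label (`"low"`, `"medium"`, `"high"`).
#' @export
light_condition <- function(intensity, source = "cool_white",
                            acclimation = "medium") {
  stopifnot(intensity >= 0)
  structure(list(intensity = intensity, source = source,
                 acclimation = acclimation), class = "light_condition")
}

#' Pigment profile: composition, spectra, and transfer efficiencies
#'
#' @param mass_fractions named numeric, pigment -> g pigment per gDW
#'   (all `>= 0`).
#' @param spectra numeric matrix, pigments x bins, weight-specific
#'   absorption (m^2 per g pigment); column names are bin lower edges.
#' @param transfer_efficiency named numeric in (0, 1]: fraction of the
#'   excitation absorbed by each pigment that reaches reaction-center
#'   chlorophyll a in the fucoxanthin chlorophyll a/c binding proteins.
#' @return object of class `"pigment_profile"`.
#' @export
pigment_profile <- function(mass_fractions, spectra, transfer_efficiency) {
  pig <- names(mass_fractions)
  if (any(mass_fractions < 0)) stop("pigment mass fractions must be >= 0")
  if (!setequal(rownames(spectra), pig) ||
      !setequal(colnames(spectra), as.character(par_bins()))) {
    stop("spectra must be a pigment x PAR-bin matrix matching the profile")
  }
  if (!all(pig %in% names(transfer_efficiency)) ||
      any(transfer_efficiency <= 0) || any(transfer_efficiency > 1)) {
    stop("transfer efficiencies must cover every pigment and lie in (0, 1]")
  }
  structure(list(mass_fractions = mass_fractions,
                 spectra = spectra[pig, as.character(par_bins()), drop = FALSE],
                 transfer_efficiency = transfer_efficiency[pig]),
            class = "pigment_profile")
}

#' Biomass-specific absorption from pigment composition
#'
#' Sums the weight-specific pigment spectra weighted by pigment mass
#' fraction, giving the biomass-specific absorption a (m^2 gDW^-1) in each
#' 20 nm bin together with each pigment's relative share of the absorption.
#'
#' @param profile a [pigment_profile()].
#' @return list with `a` (named numeric per bin, m^2 gDW^-1) and `relative`
#'   (pigments x bins matrix; columns with nonzero absorption sum to 1).
#' @export
biomass_absorption <- function(profile) {
  stopifnot(inherits(profile, "pigment_profile"))
  if (all(profile$mass_fractions == 0)) {
    warning("all pigment mass fractions are zero; absorption is zero")
  }
  contrib <- profile$spectra * profile$mass_fractions
  a <- colSums(contrib)
  rel <- contrib
  nz <- a > 0
  rel[, nz] <- sweep(contrib[, nz, drop = FALSE], 2, a[nz], "/")
  rel[, !nz] <- 0
  list(a = a, relative = rel)
}

#' Per-bin photon uptake bounds
#'
#' The lower (most-negative) bound of each photon exchange reaction is the
#' photon flux absorbed: `LB = -1 * r * I * a * 3.6`, where `r` is the
#' light-source fraction in the bin, `I` the irradiance (umol photons m^-2
#' s^-1), `a` the biomass-specific absorption (m^2 gDW^-1), and 3.6 converts
#' to mmol photons gDW^-1 h^-1. The upper bound is `0.9999 * LB`: under the
#' uptake-is-negative sign convention absorption is obligatory -- the cell
#' cannot choose not to absorb incident photons (they must be processed or
#' explicitly dissipated).
#'
#' @param grid a [spectral_grid()].
#' @param light a [light_condition()] or a plain irradiance value.
#' @return data frame: `bin_nm`, `lb`, `ub` (mmol photons gDW^-1 h^-1).
#' @export
photon_uptake_bounds <- function(grid, light) {
  stopifnot(inherits(grid, "spectral_grid"))
  I <- if (inherits(light, "light_condition")) light$intensity else light
  stopifnot(I >= 0)
  lb <- -1 * grid$r * I * grid$a * PHOTON_UNIT_BRIDGE
  data.frame(bin_nm = grid$bins, lb = unname(lb), ub = unname(0.9999 * lb))
}

#' D1 photodamage events per O2 evolved
#'
#' D1 inactivation per photon rises linearly with irradiance
#' (`events/photon = slope * I`); dividing by the quantum efficiency of
#' photosynthesis converts to events per O2 evolved at PSII.
#'
#' @param I irradiance (umol photons m^-2 s^-1).
#' @param phi_m quantum efficiency (mol O2 per mol photon), `> 0`.
#' @param slope damage events per photon per unit irradiance.
#' @return damage events per O2 evolved.
#' @export
d1_damage_per_o2 <- function(I, phi_m, slope) {
  if (phi_m <= 0) stop("phi_m must be > 0")
  events_per_photon <- slope * I
  events_per_photon / phi_m
}

#' Add mechanistic light reactions to a model
#'
#' Builds, per 20 nm bin: a photon exchange reaction (if absent) and a
#' photon absorption reaction that apportions the bin's photons to pigment
#' excitation states by relative absorption; per pigment: an excitation
#' transfer reaction to reaction-center chlorophyll a excitation with the
#' pigment's transfer efficiency as stoichiometric yield, and a
#' de-excitation reaction discarding excitation as heat/fluorescence.
#' Photon exchange bounds are set from [photon_uptake_bounds()]. The PSII
#' charge-separation reaction gains a D1-damage by-product whose repair is
#' paid for by an ATP-consuming D1 repair reaction (part of non-growth
#' maintenance).
#'
#' @param model a metabolic model containing `PSIICS` and `PSICS` reactions
#'   and a thylakoid compartment.
#' @param profile a [pigment_profile()].
#' @param source named numeric of light-source fractions per bin.
#' @param light a [light_condition()] or irradiance value.
#' @param d1_slope D1 damage events per photon per unit irradiance.
#' @param phi_m quantum efficiency (mol O2 / mol photon) for the damage
#'   conversion.
#' @param d1_repair_atp ATP (+GTP-equivalent) cost per D1 repair event.
#' @param excitons_per_o2 excitations consumed by `PSIICS` per O2 evolved.
#' @return the augmented model.
#' @export
build_light_reactions <- function(model, profile, source, light,
                                  d1_slope = 7e-7, phi_m = 0.056,
                                  d1_repair_atp = 10,
                                  excitons_per_o2 = 4) {
  need <- c("PSIICS", "PSICS")
  missing <- setdiff(need, names(model$reactions))
  if (length(missing)) {
    stop("model lacks photosystem charge-separation reaction(s): ",
         paste(missing, collapse = ", "))
  }
  abs_ <- biomass_absorption(profile)
  grid <- spectral_grid(source, abs_$a)
  I <- if (inherits(light, "light_condition")) light$intensity else light
  pbounds <- photon_uptake_bounds(grid, I)

  pigs <- names(profile$mass_fractions)
  ## excitation-state metabolites (massless, thylakoid)
  for (p in pigs) {
    exid <- paste0("ex_", p, "_u")
    if (!exid %in% model$metabolites$id) {
      model <- add_metabolite(model, metabolite(
        exid, name = paste0("excited ", p), formula = "", charge = 0,
        compartment = "u"))
    }
  }
  if (!"ex_chla_u" %in% model$metabolites$id) {
    stop("profile must include chlorophyll a ('chla'), the reaction-center pigment")
  }

  for (k in seq_along(par_bins())) {
    bin <- par_bins()[k]
    ph <- paste0("photon", bin, "_e")
    if (!ph %in% model$metabolites$id) {
      model <- add_metabolite(model, metabolite(
        ph, name = paste0("photon ", bin, "-", bin + 20, " nm"),
        formula = "", charge = 0, compartment = "e"))
    }
    exch <- paste0("EX_photon", bin, "_e")
    if (exch %in% names(model$reactions)) {
      model <- set_bounds(model, exch, pbounds$lb[k], pbounds$ub[k])
    } else {
      model <- add_reaction(model, reaction(
        exch, stats::setNames(-1, ph),
        lower_bound = pbounds$lb[k], upper_bound = pbounds$ub[k],
        name = paste0("photon exchange ", bin, " nm"),
        subsystem = "Light harvesting"))
    }
    ## absorption: photon -> pigment excitations by relative absorption
    shares <- abs_$relative[, as.character(bin)]
    shares <- shares[shares > 0]
    phoa <- paste0("PHOA", bin)
    if (phoa %in% names(model$reactions)) model <- remove_reaction(model, phoa)
    if (length(shares)) {
      st <- c(stats::setNames(-1, ph),
              stats::setNames(as.numeric(shares),
                              paste0("ex_", names(shares), "_u")))
      model <- add_reaction(model, reaction(
        phoa, st, lower_bound = 0, upper_bound = 1000,
        name = paste0("photon absorption ", bin, " nm"),
        subsystem = "Light harvesting"))
    }
  }

  for (p in pigs) {
    exid <- paste0("ex_", p, "_u")
    if (p != "chla") {
      eff <- profile$transfer_efficiency[[p]]
      tid <- paste0("EXCT_", p)
      if (tid %in% names(model$reactions)) model <- remove_reaction(model, tid)
      model <- add_reaction(model, reaction(
        tid, stats::setNames(c(-1, eff), c(exid, "ex_chla_u")),
        lower_bound = 0, upper_bound = 1000,
        name = paste0("excitation transfer ", p, " -> chl a"),
        subsystem = "Light harvesting"))
    }
    did <- paste0("DEEX_", p)
    if (!did %in% names(model$reactions)) {
      model <- add_reaction(model, reaction(
        did, stats::setNames(-1, exid), lower_bound = 0, upper_bound = 1000,
        name = paste0("de-excitation (heat/fluorescence) of ", p),
        subsystem = "Light harvesting"))
    }
  }

  ## D1 damage by-product on PSII + repair cost
  dmg <- d1_damage_per_o2(I, phi_m, d1_slope)
  psii <- model$reactions[["PSIICS"]]
  if (!"d1dam_h" %in% model$metabolites$id) {
    model <- add_metabolite(model, metabolite(
      "d1dam_h", name = "damaged D1 subunit", formula = "", charge = 0,
      compartment = "h"))
  }
  o2c <- psii$stoichiometry[grep("^o2_", names(psii$stoichiometry))]
  if (length(o2c) != 1L || o2c <= 0) {
    stop("PSIICS must evolve O2 to attach D1 damage accounting")
  }
  psii$stoichiometry <- psii$stoichiometry[
    setdiff(names(psii$stoichiometry), "d1dam_h")]
  if (dmg > 0) {
    psii$stoichiometry <- c(psii$stoichiometry,
                            stats::setNames(dmg * o2c, "d1dam_h"))
  }
  model$reactions[["PSIICS"]] <- psii
  if (!"D1REPAIR" %in% names(model$reactions)) {
    model <- add_reaction(model, reaction(
      "D1REPAIR",
      c(d1dam_h = -1,
        atp_c = -d1_repair_atp, h2o_c = -d1_repair_atp,
        adp_c = d1_repair_atp, pi_c = d1_repair_atp, h_c = d1_repair_atp),
      lower_bound = 0, upper_bound = 1000,
      name = "D1 repair (FtsH activation + peptide synthesis cost)",
      subsystem = "Maintenance"))
  }
  validate_model(model)
}

#' Built-in cool-white fluorescent source spectrum
#'
#' Photon-flux fractions per 20 nm PAR bin for a generic cool-white
#' fluorescent bulb (strong emission in the 540-620 nm region), normalized
#' to sum to 1. Editable: any named vector over [par_bins()] that sums to 1
#' can be used in its place.
#' @return named numeric over the PAR bins.
#' @export
default_light_source <- function() {
  x <- c(2, 3, 4, 4, 5, 6, 7, 9, 12, 13, 11, 9, 7, 5, 3)
  stats::setNames(x / sum(x), as.character(par_bins()))
}

#' Built-in pigment profile for a diatom-like cell
#'
#' Mass fractions, weight-specific absorption spectra, and
#' excitation-transfer efficiencies for the five main diatom pigments:
#' chlorophyll a and c, fucoxanthin, diadinoxanthin, and beta-carotene.
#' The spectra are smooth synthetic shapes with the pigments' characteristic
#' peak positions (chl a Soret/red, chl c Soret/640, broad fucoxanthin
#' 450-550 coverage, photoprotective carotenoids in the blue); they stand in
#' for instrument-grade spectra, which users can supply via
#' [pigment_profile()]. Acclimation shifts the composition the way diatoms
#' do: more total pigment at low light, more photoprotective carotenoid
#' (diadinoxanthin, beta-carotene) at high light.
#'
#' @param acclimation `"low"`, `"medium"` or `"high"` growth irradiance.
#' @return a [pigment_profile()].
#' @export
default_pigment_profile <- function(acclimation = c("medium", "low", "high")) {
  acclimation <- match.arg(acclimation)
  bins <- par_bins()
  peak <- function(center, width, height) {
    height * exp(-0.5 * ((bins + 10 - center) / width)^2)
  }
  sp <- rbind(
    chla = peak(440, 18, 22) + peak(675, 14, 16),
    chlc = peak(455, 16, 18) + peak(635, 12, 8),
    fucox = peak(460, 30, 12) + peak(520, 35, 10),
    diadino = peak(450, 22, 12),
    bcar = peak(460, 25, 10)
  )
  colnames(sp) <- as.character(bins)
  frac <- switch(acclimation,
    low    = c(chla = 0.030, chlc = 0.007, fucox = 0.016, diadino = 0.0020,
               bcar = 0.0012),
    medium = c(chla = 0.015, chlc = 0.004, fucox = 0.008, diadino = 0.0020,
               bcar = 0.0010),
    high   = c(chla = 0.008, chlc = 0.002, fucox = 0.004, diadino = 0.0045,
               bcar = 0.0020))
  eff <- c(chla = 1.0, chlc = 0.95, fucox = 0.80, diadino = 0.15, bcar = 0.20)
  pigment_profile(frac, sp, eff)
}
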