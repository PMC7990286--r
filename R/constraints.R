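## Condition-specific flux constraints: the cyclic electron flow cap,
## photorespiration coupling, plastid-mitochondrion energetic coupling,
## respiration flux-sum bounds, PSII bounds from P-I fits, and transient
## carbon sink bounds. All are linear relations over named fluxes; nothing
## kinetic.

#' Cyclic electron flow cap
#'
#' Caps CEF at a fraction of total electron flow. Total electron flow is
#' `PSICS + PSIICS - 2*CBFC2 + 2*CEF` (linear flow counted through the two
#' photosystems net of the cytochrome b6/f pass-through, plus the cyclic
#' contribution), and the cap `2*CEF <= fraction * TEF` is stored in
#' linearized inequality form:
#' `2*(1-fraction)*CEF - fraction*PSICS - fraction*PSIICS
#'  + 2*fraction*CBFC2 <= 0`.
#'
#' The workflow mirrors how such caps are derived: apply the fractional
#' cap at saturating light to find the absolute CEF flux it allows, then
#' reuse that absolute value as a hard bound at lower light, where it can
#' be a large share of the (smaller) total electron flow.
#'
#' @param model model containing reactions `CEF`, `PSICS`, `PSIICS`,
#'   `CBFC2`.
#' @param fraction maximal CEF share of total electron flow, in `[0, 1)`.
#' @return a [flux_constraint()] with id `"cef_cap"`.
#' @export
cef_constraint <- function(model, fraction = 0.05) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  need <- c("CEF", "PSICS", "PSIICS", "CBFC2")
  missing <- setdiff(need, names(model$reactions))
  if (length(missing)) {
    stop("model lacks reaction(s): ", paste(missing, collapse = ", "))
  }
  flux_constraint(
    c(CEF = 2 * (1 - fraction), PSICS = -fraction, PSIICS = -fraction,
      CBFC2 = 2 * fraction),
    lower = -Inf, upper = 0, id = "cef_cap")
}

#' Photorespiratory oxygenase:carboxylase ratio
#'
#' From RuBisCO's CO2/O2 specificity and the gas concentrations where the
#' enzyme sits: `vc/vo = specificity * [CO2]/[O2]`. The constraint
#' coefficient is the inverse, rounded to two significant figures (both
#' raw and rounded values are returned).
#'
#' @param specificity RuBisCO specificity factor `(Vc*Ko)/(Vo*Kc)`, `> 0`.
#' @param co2,o2 CO2 and O2 concentrations at the enzyme (uM); `o2 = 0`
#'   gives ratio 0 (no photorespiration), with a message.
#' @return list: `vc_vo`, `ratio_raw` (`vo/vc`), `ratio` (2 significant
#'   figures).
#' @export
photorespiration_ratio <- function(specificity, co2, o2) {
  stopifnot(specificity > 0, co2 > 0, o2 >= 0)
  if (o2 == 0) {
    message("O2 concentration is zero: no photorespiration (ratio 0)")
    return(list(vc_vo = Inf, ratio_raw = 0, ratio = 0))
  }
  vc_vo <- specificity * co2 / o2
  list(vc_vo = vc_vo, ratio_raw = 1 / vc_vo, ratio = signif(1 / vc_vo, 2))
}

#' Photorespiration constraint
#'
#' Ties the RuBisCO oxygenase flux to the carboxylase flux: an equality
#' `RUBISO = ratio * RUBISC` for steady-state runs, or an interval
#' `lo * RUBISC <= RUBISO <= hi * RUBISC` for dynamic simulations.
#'
#' @param model model containing `RUBISC_h` and `RUBISO_h`.
#' @param ratio single oxygenase:carboxylase ratio (equality form).
#' @param range length-2 numeric `c(lo, hi)`; overrides `ratio`.
#' @return a [flux_constraint()] (equality) or list of two (interval).
#' @export
photorespiration_constraint <- function(model, ratio = NULL, range = NULL) {
  need <- c("RUBISC_h", "RUBISO_h")
  missing <- setdiff(need, names(model$reactions))
  if (length(missing)) {
    stop("model lacks reaction(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1] <= range[2])
    list(
      flux_constraint(c(RUBISO_h = 1, RUBISC_h = -range[2]),
                      lower = -Inf, upper = 0, id = "photoresp_hi"),
      flux_constraint(c(RUBISO_h = 1, RUBISC_h = -range[1]),
                      lower = 0, upper = Inf, id = "photoresp_lo"))
  } else {
    stopifnot(!is.null(ratio), ratio >= 0)
    flux_constraint(c(RUBISO_h = 1, RUBISC_h = -ratio), lower = 0, upper = 0,
                    id = "photoresp")
  }
}

#' Plastid-mitochondrion energetic coupling constraint
#'
#' Redirects a fixed fraction of PSI electron flow to the mitochondrial
#' NADH:ubiquinone oxidoreductase: `NADHOR = k * PSI` (equality).
#'
#' @param model model containing the two reactions.
#' @param k coupling coefficient, `>= 0`.
#' @param nadhor_id,psi_id reaction ids.
#' @return a [flux_constraint()] with id `"energetic_coupling"`.
#' @export
energetic_coupling_constraint <- function(model, k, nadhor_id = "NADHOR_m",
                                          psi_id = "PSICS") {
  if (k < 0) stop("coupling coefficient k must be >= 0")
  missing <- setdiff(c(nadhor_id, psi_id), names(model$reactions))
  if (length(missing)) {
    stop("model lacks reaction(s): ", paste(missing, collapse = ", "))
  }
  cf <- stats::setNames(c(1, -k), c(nadhor_id, psi_id))
  flux_constraint(cf, lower = 0, upper = 0, id = "energetic_coupling")
}

#' Default reaction category map of the mini-phototroph
#'
#' Weighted reaction sets used by the respiration constraints and the
#' electron budget. Weights convert each reaction's flux to the measured
#' quantity: O2 consumed per unit flux for the respiration sum, CO2
#' produced per unit flux for the TCA dehydrogenase sum, and electrons per
#' unit flux for the budget categories. For other models, supply a map
#' with the same shape.
#'
#' @return nested list: `o2_reducing`, `tca_dehydrogenase`,
#'   `electron_sinks` (category -> named weight vector), `electron_sources`.
#' @export
toy_category_map <- function() {
  list(
    o2_reducing = c(MEHLER_h = 1, PTOX_h = 0.5, AOX_m = 0.5, CYOO_m = 0.5,
                    GLYCTO_x = 1),
    tca_dehydrogenase = c(TCADH_m = 3),
    electron_sinks = list(
      CEF = c(CEF = 2),
      Mehler = c(MEHLER_h = 4),
      PTOX = c(PTOX_h = 2),
      AOX = c(AOX_m = 2),
      cytochrome_c_oxidase = c(CYOO_m = 2),
      glycolate_oxidase = c(GLYCTO_x = 2),
      RuBisCO_oxygenase = c(RUBISO_h = 2),
      NO3_reduction = c(NR_c = 2),
      NO2_reduction = c(NiR_h = 6),
      glutamate_synthesis = c(GOGAT_h = 2),
      APS_reduction = c(APSR_h = 2),
      SO3_reduction = c(SO3R_h = 6),
      sulfotransferase = c(SLFT_h = 2),
      C_assimilation = c(RUBISC_h = 4)
    ),
    electron_sources = c(PSIICS = 1, SK_chryso_c = 24, SK_g3p_c = 12)
  )
}

#' Respiration flux-sum constraints from production measurements
#'
#' Builds (1) a lower bound on the weighted sum of all O2-reducing
#' (light-driven respiration) reactions equal to the measured
#' light-dependent respiration, and (2) a two-sided bound on the weighted
#' sum of CO2-producing mitochondrial TCA dehydrogenases equal to the
#' confidence interval of mitochondrial maintenance respiration.
#'
#' @param model a metabolic model.
#' @param light_dependent_respiration measured light-dependent respiration
#'   (mmol O2 gDW^-1 h^-1), the lower bound of constraint (1).
#' @param mito_maintenance_ci length-2 interval (CO2-equivalent flux) for
#'   constraint (2).
#' @param category_map list with `o2_reducing` and `tca_dehydrogenase`
#'   named weight vectors (see [toy_category_map()]).
#' @return list of two [flux_constraint()]s (`respiration_sum`, `tca_sum`).
#' @export
respiration_constraints <- function(model, light_dependent_respiration,
                                    mito_maintenance_ci,
                                    category_map = toy_category_map()) {
  for (k in c("o2_reducing", "tca_dehydrogenase")) {
    if (!length(category_map[[k]])) stop("empty reaction category: ", k)
    missing <- setdiff(names(category_map[[k]]), names(model$reactions))
    if (length(missing)) {
      stop("category '", k, "' references unknown reaction(s): ",
           paste(missing, collapse = ", "))
    }
  }
  stopifnot(light_dependent_respiration >= 0,
            length(mito_maintenance_ci) == 2L,
            mito_maintenance_ci[1] <= mito_maintenance_ci[2],
            all(mito_maintenance_ci >= 0))
  list(
    respiration_sum = flux_constraint(
      category_map$o2_reducing, lower = light_dependent_respiration,
      upper = Inf, id = "respiration_sum"),
    tca_sum = flux_constraint(
      category_map$tca_dehydrogenase, lower = mito_maintenance_ci[1],
      upper = mito_maintenance_ci[2], id = "tca_sum"))
}

#' PSII bounds from a fitted P-I curve
#'
#' The PSII reaction is bounded by the 95% confidence interval of gross
#' photosynthesis at the growth irradiance, propagated from the fit's
#' parameter covariance and unit-converted if needed.
#'
#' @param fit a [fit_platt()] (or any `pi_fit`).
#' @param I irradiance (`>= 0`).
#' @param conversion multiplicative unit conversion applied to both bounds
#'   (e.g. mg chl a to gDW).
#' @param level confidence level.
#' @return numeric `c(lb, ub)` in converted units.
#' @export
psii_bounds_from_fit <- function(fit, I, conversion = 1, level = 0.95) {
  if (I < 0) stop("irradiance must be >= 0")
  pr <- predict(fit, I, interval = "confidence", level = level)
  c(lb = max(pr$lwr, 0) * conversion, ub = pr$upr * conversion)
}

#' Transient carbon sink bounds
#'
#' Splits a measured carbon catabolism flux between the chrysolaminarin
#' sink (used by dividing cells) and the glyceraldehyde-3-phosphate sink
#' (used by non-dividing cells), proportionally to the fraction of the
#' population dividing, and scales so total sink carbon matches the
#' measurement. Sinks supply at negative flux, so the bounds are lower
#' bounds.
#'
#' @param model model containing the two sink reactions.
#' @param catabolism carbon catabolism (mmol C gDW^-1 h^-1), `>= 0`.
#' @param dividing_fraction fraction of cells dividing, in `[0, 1]`.
#' @param chryso_id,g3p_id sink reaction ids.
#' @param chryso_c,g3p_c carbon atoms per sink species unit.
#' @return the model with sink bounds applied; the bounds are attached as
#'   attribute `"sink_bounds"`.
#' @export
transient_carbon_sinks <- function(model, catabolism, dividing_fraction,
                                   chryso_id = "SK_chryso_c",
                                   g3p_id = "SK_g3p_c",
                                   chryso_c = 6, g3p_c = 3) {
  if (dividing_fraction < 0 || dividing_fraction > 1) {
    stop("dividing_fraction must lie in [0, 1]")
  }
  stopifnot(catabolism >= 0)
  missing <- setdiff(c(chryso_id, g3p_id), names(model$reactions))
  if (length(missing)) {
    stop("model lacks sink reaction(s): ", paste(missing, collapse = ", "))
  }
  lb_ch <- -dividing_fraction * catabolism / chryso_c
  lb_g3 <- -(1 - dividing_fraction) * catabolism / g3p_c
  model <- set_bounds(model, chryso_id, lower = lb_ch, upper = 0)
  model <- set_bounds(model, g3p_id, lower = lb_g3, upper = 0)
  attr(model, "sink_bounds") <- c(stats::setNames(lb_ch, chryso_id),
                                  stats::setNames(lb_g3, g3p_id))
  model
}
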