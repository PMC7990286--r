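## Post-processing: electron budgets of flux solutions and secretion
## profiles of dynamic-FBA trajectories.

#' Electron budget of a flux solution
#'
#' Sums `weight * |flux|` over the member reactions of each reductant-sink
#' category (cyclic electron flow, the water-forming oxidases, RuBisCO
#' oxygenase, the nitrate/nitrite/glutamate assimilation chain, the
#' sulfate assimilation chain, carbon assimilation), in mmol electrons
#' gDW^-1 h^-1. Electron sources (PSII water splitting plus any transient
#' organic-carbon sinks being respired) are totalled the same way, and
#' "biosynthesis" is reported as the residual sources minus named sinks,
#' mirroring how reductant budgets group biomass production.
#'
#' @param sol an optimal `flux_solution`.
#' @param category_map list with `electron_sinks` (category -> named
#'   per-reaction electron weights) and `electron_sources`; see
#'   [toy_category_map()]. A reaction may appear in only one sink
#'   category.
#' @return object of class `"electron_budget"`: named numeric of category
#'   values plus `biosynthesis`, with attribute `sources` (total source
#'   electrons).
#' @export
electron_budget <- function(sol, category_map = toy_category_map()) {
  stopifnot(sol$status == "optimal")
  sinks <- category_map$electron_sinks
  all_members <- unlist(lapply(sinks, names))
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup)) {
    stop("reaction(s) mapped to more than one category: ",
         paste(dup, collapse = ", "))
  }
  val <- vapply(sinks, function(w) {
    ids <- intersect(names(w), names(sol$fluxes))
    sum(w[ids] * abs(sol$fluxes[ids]))
  }, numeric(1))
  srcw <- category_map$electron_sources
  ids <- intersect(names(srcw), names(sol$fluxes))
  sources <- sum(srcw[ids] * abs(sol$fluxes[ids]))
  out <- c(val, biosynthesis = max(sources - sum(val), 0))
  structure(out, sources = sources, class = "electron_budget")
}

#' @export
print.electron_budget <- function(x, ...) {
  cat("<electron_budget> (mmol e- gDW^-1 h^-1; sources ",
      format(attr(x, "sources"), digits = 4), ")\n", sep = "")
  v <- sort(unclass(x), decreasing = TRUE)
  for (nm in names(v)) {
    if (v[[nm]] > 0) cat(sprintf("  %-22s %10.5f\n", nm, v[[nm]]))
  }
  invisible(x)
}

#' Secretion profile of a dynamic-FBA trajectory
#'
#' Extracts the environment concentration time series of exchanged
#' non-nutrient metabolites, classifies each by elemental content
#' (organic C / organic N / organic S / inorganic), and flags metabolites
#' with excrete-then-reassimilate episodes (sign changes of the exchange
#' flux across intervals), the signature of diel cycling of compounds such
#' as ethanol. A pure view: the trajectory is not modified.
#'
#' @param traj a `dfba_trajectory`.
#' @param metabolites environment metabolites to profile; defaults to
#'   everything that is not a standing nutrient/gas pool.
#' @param formulas named formulas used for classification (defaults to the
#'   mini-phototroph catalog).
#' @return data frame of class `"secretion_profile"`: `t` (h),
#'   `metabolite`, `conc_uM`, `class`, `diel` (logical).
#' @export
secretion_profile <- function(traj, metabolites = NULL, formulas = NULL) {
  env_names <- names(traj$states[[1]]$environment)
  if (is.null(metabolites)) {
    nutrients <- c("no3", "no2", "nh4", "pi", "sioh4", "so4", "mg2", "co2",
                   "hco3", "o2", "h2o", "h", "frus")
    metabolites <- setdiff(env_names, nutrients)
  }
  if (is.null(formulas)) {
    tab <- toy_metabolite_table()
    formulas <- stats::setNames(tab$formula, tab$base)
  }
  classify <- function(f) {
    ct <- parse_formula(f)
    has <- function(el) el %in% names(ct) && ct[[el]] > 0
    if (has("C") && has("S")) "organic_S"
    else if (has("C") && has("N")) "organic_N"
    else if (has("C")) "organic_C"
    else "inorganic"
  }
  diel_flag <- vapply(metabolites, function(mt) {
    ex <- paste0("EX_", mt, "_e")
    fl <- vapply(traj$solutions, function(s) {
      if (ex %in% names(s$fluxes)) s$fluxes[[ex]] else 0
    }, numeric(1))
    any(fl > 1e-9) && any(fl < -1e-9)
  }, logical(1))
  rows <- do.call(rbind, lapply(seq_along(traj$states), function(i) {
    s <- traj$states[[i]]
    data.frame(t = s$t, metabolite = metabolites,
               conc_uM = 1000 * as.numeric(s$environment[metabolites]),
               stringsAsFactors = FALSE)
  }))
  rows$class <- vapply(formulas[rows$metabolite], classify, character(1))
  rows$diel <- diel_flag[rows$metabolite]
  class(rows) <- c("secretion_profile", "data.frame")
  rows
}

#' Write tidy delimited reports
#'
#' @param x an `electron_budget`, `secretion_profile`, or model summary
#'   data frame.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "electron_budget")) {
    x <- data.frame(category = names(x), mmol_e_gDW_h = as.numeric(x))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
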