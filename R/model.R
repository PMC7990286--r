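## Core containers: metabolites, reactions, models, and auxiliary linear
## flux-sum constraints.  Conventions follow the COBRA community standard:
## negative stoichiometric coefficients consume, negative flux runs a
## reaction in reverse, and a negative exchange flux is uptake.

#' Create a metabolite
#'
#' @param id unique metabolite id (by convention `<name>_<compartment>`).
#' @param name human-readable name.
#' @param formula elemental formula string (`""` for massless bookkeeping
#'   species such as photons or excitation states; fractional counts allowed
#'   for lumped species).
#' @param charge integer formal charge.
#' @param compartment compartment code; the diatom-style set is
#'   `c` cytosol, `h` plastid, `u` thylakoid lumen, `m` mitochondrion,
#'   `x` peroxisome, `r` endoplasmic reticulum, `e` extracellular.
#' @return object of class `"metabolite"`.
#' @export
metabolite <- function(id, name = id, formula = "", charge = 0L,
                       compartment = "c") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  parse_formula(formula)  # validates
  structure(list(id = id, name = name, formula = formula,
                 charge = as.numeric(charge), compartment = compartment),
            class = "metabolite")
}

#' Create a reaction
#'
#' @param id unique reaction id.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient
#'   (negative = consumed). Must be non-empty.
#' @param lower_bound,upper_bound flux bounds in mmol gDW^-1 h^-1.
#' @param name human-readable name.
#' @param gene_association optional boolean gene-association string
#'   (e.g. `"(g1 and g2) or g3"`).
#' @param subsystem optional subsystem label.
#' @return object of class `"fba_reaction"`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -1000,
                     upper_bound = 1000, name = id,
                     gene_association = NA_character_,
                     subsystem = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!length(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector")
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound")
  }
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound), name = name,
                 gene_association = gene_association, subsystem = subsystem),
            class = "fba_reaction")
}

#' Create a weighted flux-sum constraint
#'
#' A linear constraint `lower <= sum_i w_i * v_i <= upper` over named
#' reaction fluxes, added to a model with [add_flux_constraint()]. This is
#' the mechanism behind condition constraints such as the cyclic electron
#' flow cap or the respiration flux-sum bounds.
#'
#' @param coefficients named numeric vector, reaction id -> weight; at least
#'   one weight must be nonzero.
#' @param lower,upper constraint bounds; either may be infinite.
#' @param id optional identifier (used by [remove_flux_constraint()]).
#' @return object of class `"flux_constraint"`.
#' @export
flux_constraint <- function(coefficients, lower = -Inf, upper = Inf,
                            id = NULL) {
  if (!length(coefficients) || is.null(names(coefficients))) {
    stop("coefficients must be a named numeric vector")
  }
  if (all(abs(coefficients) < 1e-15)) stop("all constraint coefficients are zero")
  if (lower > upper) stop("constraint lower bound exceeds upper bound")
  structure(list(coefficients = coefficients, lower = as.numeric(lower),
                 upper = as.numeric(upper), id = id),
            class = "flux_constraint")
}

#' Assemble a metabolic model
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param objective named numeric vector, reaction id -> objective
#'   coefficient (maximized by [solve_fba()]).
#' @param compartments optional named character vector of compartment
#'   descriptions; inferred from the metabolites when missing.
#' @param extra_constraints list of [flux_constraint()] objects.
#' @param id model identifier.
#' @return object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = numeric(0),
                            compartments = NULL, extra_constraints = list(),
                            id = "model") {
  mets <- do.call(rbind, lapply(metabolites, function(m) {
    stopifnot(inherits(m, "metabolite"))
    data.frame(id = m$id, name = m$name, formula = m$formula,
               charge = m$charge, compartment = m$compartment,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  rxns <- stats::setNames(reactions, vapply(reactions, `[[`, "", "id"))
  if (anyDuplicated(names(rxns))) {
    stop("duplicate reaction ids: ",
         paste(unique(names(rxns)[duplicated(names(rxns))]), collapse = ", "))
  }
  if (is.null(compartments)) {
    cps <- sort(unique(mets$compartment))
    compartments <- stats::setNames(cps, cps)
  }
  model <- structure(list(id = id, metabolites = mets, reactions = rxns,
                          objective = objective,
                          compartments = compartments,
                          extra_constraints = extra_constraints),
                     class = "metabolic_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  met_ids <- model$metabolites$id
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing)) {
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
    }
  }
  bad <- setdiff(names(model$objective), names(model$reactions))
  if (length(bad)) {
    stop("objective references unknown reaction(s): ",
         paste(bad, collapse = ", "))
  }
  for (ct in model$extra_constraints) {
    bad <- setdiff(names(ct$coefficients), names(model$reactions))
    if (length(bad)) {
      stop("flux constraint references unknown reaction(s): ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", length(x$reactions),
      "   genes: ", length(model_genes(x)), "\n", sep = "")
  cat("  compartments: ", paste(names(x$compartments), collapse = ", "), "\n",
      sep = "")
  if (length(x$objective)) {
    cat("  objective: ",
        paste(sprintf("%g*%s", x$objective, names(x$objective)),
              collapse = " + "), "\n", sep = "")
  }
  if (length(x$extra_constraints)) {
    cat("  extra flux constraints: ", length(x$extra_constraints), "\n",
        sep = "")
  }
  invisible(x)
}

#' Extract gene ids from a model's gene-association strings
#' @param model a metabolic model.
#' @return character vector of unique gene ids.
#' @export
model_genes <- function(model) {
  gpr <- vapply(model$reactions, `[[`, "", "gene_association")
  gpr <- gpr[!is.na(gpr) & nzchar(gpr)]
  if (!length(gpr)) return(character(0))
  toks <- unlist(strsplit(gpr, "[()\\s]+", perl = TRUE))
  sort(unique(setdiff(toks[nzchar(toks)], c("and", "or", "AND", "OR"))))
}

#' Model summary counts
#'
#' Counts of reactions, metabolites, genes, and compartments, as a one-row
#' data frame suitable for writing as delimited text.
#' @param object a metabolic model.
#' @param ... unused.
#' @export
summary.metabolic_model <- function(object, ...) {
  data.frame(model = object$id,
             reactions = length(object$reactions),
             metabolites = nrow(object$metabolites),
             genes = length(model_genes(object)),
             compartments = length(unique(object$metabolites$compartment)),
             exchanges = sum(is_exchange(object)),
             stringsAsFactors = FALSE)
}

#' Identify exchange/sink/demand reactions
#'
#' Boundary reactions are flagged structurally: a single metabolite in the
#' stoichiometry.
#' @param model a metabolic model.
#' @return named logical vector over reaction ids.
#' @export
is_exchange <- function(model) {
  vapply(model$reactions, function(r) length(r$stoichiometry) == 1L,
         logical(1))
}

#' Dense stoichiometric matrix
#' @param model a metabolic model.
#' @return numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), length(model$reactions),
              dimnames = list(model$metabolites$id, names(model$reactions)))
  for (r in model$reactions) S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

#' Get or set reaction flux bounds
#' @param model a metabolic model.
#' @param id reaction id.
#' @param lower,upper new bounds; `NULL` leaves a bound unchanged.
#' @return `set_bounds` returns the modified model; `get_bounds` a
#'   two-column data frame over all reactions.
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  if (!id %in% names(model$reactions)) stop("unknown reaction: ", id)
  r <- model$reactions[[id]]
  if (!is.null(lower)) r$lower_bound <- as.numeric(lower)
  if (!is.null(upper)) r$upper_bound <- as.numeric(upper)
  if (r$lower_bound > r$upper_bound) {
    stop("reaction '", id, "': lower bound would exceed upper bound")
  }
  model$reactions[[id]] <- r
  model
}

#' @rdname set_bounds
#' @export
get_bounds <- function(model) {
  data.frame(reaction = names(model$reactions),
             lower = vapply(model$reactions, `[[`, 0, "lower_bound"),
             upper = vapply(model$reactions, `[[`, 0, "upper_bound"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Add or remove reactions and metabolites
#' @param model a metabolic model.
#' @param rxn a [reaction()].
#' @param met a [metabolite()].
#' @param id id to remove.
#' @return the modified model.
#' @export
add_reaction <- function(model, rxn) {
  stopifnot(inherits(rxn, "fba_reaction"))
  if (rxn$id %in% names(model$reactions)) {
    stop("reaction id already present: ", rxn$id)
  }
  model$reactions[[rxn$id]] <- rxn
  validate_model(model)
  model
}

#' @rdname add_reaction
#' @export
remove_reaction <- function(model, id) {
  if (!id %in% names(model$reactions)) stop("unknown reaction: ", id)
  model$reactions[[id]] <- NULL
  model$objective <- model$objective[setdiff(names(model$objective), id)]
  model
}

#' @rdname add_reaction
#' @export
add_metabolite <- function(model, met) {
  stopifnot(inherits(met, "metabolite"))
  if (met$id %in% model$metabolites$id) {
    stop("metabolite id already present: ", met$id)
  }
  model$metabolites <- rbind(model$metabolites,
                             data.frame(id = met$id, name = met$name,
                                        formula = met$formula,
                                        charge = met$charge,
                                        compartment = met$compartment,
                                        stringsAsFactors = FALSE))
  model
}

#' Replace the objective of a model
#' @param model a metabolic model.
#' @param objective named numeric vector (reaction id -> coefficient).
#' @export
set_objective <- function(model, objective) {
  bad <- setdiff(names(objective), names(model$reactions))
  if (length(bad)) stop("unknown reaction(s) in objective: ",
                        paste(bad, collapse = ", "))
  model$objective <- objective
  model
}

#' Attach an auxiliary flux-sum constraint to a model
#'
#' Subsequent [solve_fba()]/[solve_pfba()] calls respect
#' `lower <= sum(w * v) <= upper`.
#'
#' @param model a metabolic model.
#' @param constraint a [flux_constraint()].
#' @return the modified model.
#' @export
add_flux_constraint <- function(model, constraint) {
  stopifnot(inherits(constraint, "flux_constraint"))
  bad <- setdiff(names(constraint$coefficients), names(model$reactions))
  if (length(bad)) {
    stop("flux constraint references unknown reaction(s): ",
         paste(bad, collapse = ", "))
  }
  model$extra_constraints <- c(model$extra_constraints, list(constraint))
  model
}

#' @rdname add_flux_constraint
#' @param id constraint id to remove.
#' @export
remove_flux_constraint <- function(model, id) {
  keep <- vapply(model$extra_constraints,
                 function(ct) is.null(ct$id) || !identical(ct$id, id),
                 logical(1))
  if (all(keep)) stop("no flux constraint with id: ", id)
  model$extra_constraints <- model$extra_constraints[keep]
  model
}
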