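## FBA and pFBA over the LP core, plus network sanity checks.

## Build the equality-form LP for a model:
## variables = reactions, then one slack per extra flux-sum constraint
## (w'v - s = 0, s in [lower, upper]).
fba_lp <- function(model) {
  S <- stoich_matrix(model)
  n <- ncol(S)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  nex <- length(model$extra_constraints)
  if (nex) {
    Sx <- rbind(cbind(S, matrix(0, nrow(S), nex)),
                matrix(0, nex, n + nex))
    for (k in seq_len(nex)) {
      ct <- model$extra_constraints[[k]]
      Sx[nrow(S) + k, match(names(ct$coefficients), colnames(S))] <-
        ct$coefficients
      Sx[nrow(S) + k, n + k] <- -1
    }
    lb <- c(lb, vapply(model$extra_constraints, `[[`, 0, "lower"))
    ub <- c(ub, vapply(model$extra_constraints, `[[`, 0, "upper"))
    list(A = Sx, b = rep(0, nrow(Sx)), lb = lb, ub = ub, n = n,
         nmet = nrow(S))
  } else {
    list(A = S, b = rep(0, nrow(S)), lb = lb, ub = ub, n = n, nmet = nrow(S))
  }
}

new_flux_solution <- function(status, objective_value, fluxes, model = NULL,
                              sum_abs_flux = NA_real_) {
  sv <- NA_real_
  if (!is.null(model) && status == "optimal") {
    sv <- max(abs(stoich_matrix(model) %*% fluxes[names(model$reactions)]))
  }
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes, max_abs_sv = sv,
                 sum_abs_flux = sum_abs_flux),
            class = "flux_solution")
}

#' Flux balance analysis
#'
#' Maximizes the model objective subject to steady state (`S v = 0`), the
#' reaction bounds, and any auxiliary flux-sum constraints attached with
#' [add_flux_constraint()].
#'
#' @param model a [metabolic_model()] with a non-empty objective.
#' @param objective optional named numeric vector overriding the model
#'   objective for this solve.
#' @param tol solver tolerance (default `1e-8`).
#' @return object of class `"flux_solution"`: `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value`, named `fluxes`
#'   (mmol gDW^-1 h^-1), and `max_abs_sv`, the largest steady-state residual.
#' @seealso [solve_pfba()]
#' @export
solve_fba <- function(model, objective = NULL, tol = 1e-8) {
  if (!is.null(objective)) model <- set_objective(model, objective)
  if (!length(model$objective)) {
    stop("model has an empty objective; set one with set_objective()")
  }
  lp <- fba_lp(model)
  obj <- numeric(ncol(lp$A))
  obj[match(names(model$objective), names(model$reactions))] <-
    model$objective
  res <- lp_solve(obj, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE, tol = tol)
  if (res$status != "optimal") {
    return(new_flux_solution(res$status, NA_real_,
                             stats::setNames(rep(NA_real_, lp$n),
                                             names(model$reactions))))
  }
  fl <- stats::setNames(res$x[seq_len(lp$n)], names(model$reactions))
  new_flux_solution("optimal", res$objval, fl, model,
                    sum_abs_flux = sum(abs(fl)))
}

#' Parsimonious flux balance analysis
#'
#' Two-phase FBA: phase 1 finds the optimal objective value; phase 2 fixes
#' the objective at `(1 - fix_tol)` times that value and minimizes the total
#' absolute flux, with every reaction split into non-negative forward and
#' reverse parts. The near-exact fixing avoids numerical infeasibility from
#' fixing the optimum exactly.
#'
#' @inheritParams solve_fba
#' @param fix_tol relative slack used when fixing the phase-1 optimum.
#' @return a `"flux_solution"`; `sum_abs_flux` holds the minimized total
#'   absolute flux.
#' @export
solve_pfba <- function(model, objective = NULL, tol = 1e-8,
                       fix_tol = 1e-6) {
  if (!is.null(objective)) model <- set_objective(model, objective)
  p1 <- solve_fba(model, tol = tol)
  if (p1$status != "optimal") return(p1)
  opt <- p1$objective_value

  lp <- fba_lp(model)
  n <- lp$n; nslack <- ncol(lp$A) - n
  ## split v = vf - vr, vf/vr >= 0
  lbv <- lp$lb[seq_len(n)]; ubv <- lp$ub[seq_len(n)]
  Av <- lp$A[, seq_len(n), drop = FALSE]
  As <- if (nslack) lp$A[, n + seq_len(nslack), drop = FALSE] else NULL
  A2 <- cbind(Av, -Av, As)
  lb2 <- c(pmax(0, lbv), pmax(0, -ubv),
           if (nslack) lp$lb[n + seq_len(nslack)])
  ub2 <- c(pmax(0, ubv), pmax(0, -lbv),
           if (nslack) lp$ub[n + seq_len(nslack)])
  ## objective-fixing row: c'(vf - vr) - s = 0, s in [opt - slack, Inf)
  cvec <- numeric(n)
  cvec[match(names(model$objective), names(model$reactions))] <-
    model$objective
  slack <- max(abs(opt), 1) * fix_tol
  A2 <- rbind(cbind(A2, 0), 0)
  A2[nrow(A2), ] <- c(cvec, -cvec, rep(0, nslack), -1)
  lb2 <- c(lb2, opt - slack)
  ub2 <- c(ub2, Inf)
  b2 <- c(lp$b, 0)

  obj2 <- c(rep(1, 2 * n), rep(0, nslack + 1L))
  res <- lp_solve(obj2, A2, b2, lb2, ub2, maximize = FALSE, tol = tol)
  if (res$status != "optimal") {
    return(new_flux_solution(res$status, NA_real_,
                             stats::setNames(rep(NA_real_, n),
                                             names(model$reactions))))
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  fl <- stats::setNames(v, names(model$reactions))
  new_flux_solution("optimal", sum(cvec * v), fl, model,
                    sum_abs_flux = sum(abs(v)))
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective: ", format(x$objective_value, digits = 8), "\n", sep = "")
    cat("  sum |v|:  ", format(x$sum_abs_flux, digits = 8),
        "   max |S v|: ", format(x$max_abs_sv, digits = 3), "\n", sep = "")
    nz <- x$fluxes[abs(x$fluxes) > 1e-9]
    cat("  nonzero fluxes: ", length(nz), " of ", length(x$fluxes), "\n",
        sep = "")
  }
  invisible(x)
}

#' Detect energy-generating cycles
#'
#' Closes every exchange reaction (both bounds set to zero) and maximizes
#' each declared energy-dissipation reaction (for instance the ATP
#' hydrolysis maintenance reaction `ATPM`). A strictly positive optimum
#' means the network can create energy currency from nothing: a
#' thermodynamically infeasible energy-generating cycle. The reactions
#' implicated are those carrying flux in a parsimonious witness solution.
#'
#' Repairs (making a transport irreversible, capping an apyrase) are
#' reported for the caller to apply, never applied automatically.
#'
#' @param model a metabolic model.
#' @param dissipation_ids character vector of energy-dissipation reaction
#'   ids to probe.
#' @param tol detection threshold on the cycle objective.
#' @return list of per-dissipation-reaction results: `reaction`,
#'   `objective_value`, `cycle` (logical) and `implicated` (reaction ids
#'   with nonzero flux in the witness).
#' @export
detect_energy_generating_cycles <- function(model,
                                            dissipation_ids = "ATPM",
                                            tol = 1e-6) {
  missing <- setdiff(dissipation_ids, names(model$reactions))
  if (length(missing) == length(dissipation_ids)) {
    stop("no declared energy-dissipation reaction found in the model (",
         paste(dissipation_ids, collapse = ", "), ")")
  }
  dissipation_ids <- setdiff(dissipation_ids, missing)
  closed <- model
  for (id in names(which(is_exchange(model)))) {
    closed <- set_bounds(closed, id, 0, 0)
  }
  lapply(stats::setNames(dissipation_ids, dissipation_ids), function(id) {
    probe <- set_objective(closed, stats::setNames(1, id))
    sol <- solve_pfba(probe)
    obj <- if (sol$status == "optimal") sol$objective_value else 0
    implicated <- if (sol$status == "optimal" && obj > tol) {
      names(which(abs(sol$fluxes) > tol))
    } else character(0)
    list(reaction = id, objective_value = obj, cycle = obj > tol,
         implicated = implicated)
  })
}

#' Check mass and charge balance of every reaction
#'
#' Per reaction, sums `coefficient * atom_count` for every element and
#' `coefficient * charge`; a reaction is balanced iff every entry is within
#' `tol` of zero. Boundary reactions (single-metabolite) and reactions named
#' in `exempt` (by default anything matching "biomass") are exempt. A
#' non-exempt reaction touching a metabolite with no formula is flagged
#' unverifiable, not balanced.
#'
#' @param model a metabolic model.
#' @param exempt additional reaction ids to exempt.
#' @param exempt_pattern regular expression of exempt reaction ids.
#' @param tol numeric tolerance on each element/charge sum.
#' @return data frame with one row per reaction: `reaction`, `exempt`,
#'   `verifiable`, `balanced`, `max_imbalance`, and `detail` (list column of
#'   named per-element/charge sums).
#' @export
check_mass_charge_balance <- function(model, exempt = character(0),
                                      exempt_pattern = "biomass|^bof",
                                      tol = 1e-6) {
  met_formula <- stats::setNames(model$metabolites$formula,
                                 model$metabolites$id)
  met_charge <- stats::setNames(model$metabolites$charge,
                                model$metabolites$id)
  exch <- is_exchange(model)
  rows <- lapply(model$reactions, function(r) {
    ex <- exch[[r$id]] || r$id %in% exempt ||
      grepl(exempt_pattern, r$id, ignore.case = TRUE)
    if (ex) {
      return(data.frame(reaction = r$id, exempt = TRUE, verifiable = TRUE,
                        balanced = TRUE, max_imbalance = 0,
                        stringsAsFactors = FALSE))
    }
    ids <- names(r$stoichiometry)
    ## a species with an empty formula AND zero charge is a declared
    ## massless bookkeeping species (photon, excitation); it never makes a
    ## reaction unverifiable
    has_formula <- nzchar(met_formula[ids]) | met_charge[ids] != 0 |
      vapply(met_formula[ids], function(f) !is.na(f), logical(1))
    if (any(is.na(met_formula[ids]))) {
      return(data.frame(reaction = r$id, exempt = FALSE, verifiable = FALSE,
                        balanced = FALSE, max_imbalance = NA_real_,
                        stringsAsFactors = FALSE))
    }
    tot <- stats::setNames(numeric(0), character(0))
    for (i in seq_along(ids)) {
      tot <- formula_add(tot, parse_formula(met_formula[[ids[i]]]),
                         w = r$stoichiometry[[i]])
    }
    chg <- sum(r$stoichiometry * met_charge[ids])
    detail <- c(tot, charge = chg)
    mx <- if (length(detail)) max(abs(detail)) else 0
    data.frame(reaction = r$id, exempt = FALSE, verifiable = TRUE,
               balanced = mx <= tol, max_imbalance = mx,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$detail <- lapply(model$reactions, function(r) {
    ids <- names(r$stoichiometry)
    if (any(is.na(met_formula[ids]))) return(NULL)
    tot <- stats::setNames(numeric(0), character(0))
    for (i in seq_along(ids)) {
      tot <- formula_add(tot, parse_formula(met_formula[[ids[i]]]),
                         w = r$stoichiometry[[i]])
    }
    c(tot, charge = sum(r$stoichiometry * met_charge[ids]))
  })
  out
}
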