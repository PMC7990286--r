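## ATP maintenance calibration: photosynthesis-irradiance curve fits
## (saturating-exponential and hyperbolic-tangent forms), compensation
## irradiance, the closed-form non-growth maintenance bound, maintenance
## regression, and per-condition iterative GAM calibration.

pi_fit_object <- function(fit, data, form, class) {
  est <- stats::coef(fit)
  structure(list(coefficients = est, vcov = stats::vcov(fit),
                 sigma = stats::sigma(fit), df = stats::df.residual(fit),
                 data = data, form = form, nls = fit),
            class = c(class, "pi_fit"))
}

## multi-start nonlinear least squares; starts built from data heuristics
fit_pi_curve <- function(data, formula, starts, class, form) {
  if (nrow(data) < 3L) stop("need at least 3 (I, rate) points")
  if (all(abs(data[[2]]) < 1e-12)) stop("degenerate data: all rates are zero")
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) &&
        (is.null(best) || stats::deviance(f) < stats::deviance(best))) {
      best <- f
    }
  }
  if (is.null(best)) {
    stop("photosynthesis-irradiance fit did not converge from any start")
  }
  pi_fit_object(best, data, form, class)
}

#' Fit the saturating-exponential photosynthesis-irradiance curve
#'
#' Nonlinear least squares of `GPP = Ps * (1 - exp(-alpha * I / Ps))` to
#' gross photosynthesis measurements. Starting values come from the data
#' (Ps near the plateau, alpha from the initial slope), with a small grid
#' of perturbed starts to avoid convergence traps.
#'
#' @param I irradiance (umol photons m^-2 s^-1), or a two-column data frame
#'   `(I, gpp)`.
#' @param gpp gross photosynthesis (mmol O2 gDW^-1 h^-1, or any consistent
#'   flux unit).
#' @return object of class `c("platt_fit", "pi_fit")` with `coefficients`
#'   (`Ps`, `alpha`), `vcov`, and the data; see [predict.pi_fit()].
#' @export
fit_platt <- function(I, gpp = NULL) {
  d <- if (is.data.frame(I)) stats::setNames(I[, 1:2], c("I", "y")) else
    data.frame(I = I, y = gpp)
  ps0 <- max(d$y)
  low <- d$I > 0 & d$I <= stats::quantile(d$I[d$I > 0], 0.4)
  a0 <- if (any(low)) stats::median(d$y[low] / d$I[low]) else ps0 / max(d$I)
  a0 <- max(a0, 1e-6)
  starts <- list(list(Ps = ps0, alpha = a0),
                 list(Ps = ps0 * 1.5, alpha = a0 * 0.5),
                 list(Ps = ps0 * 0.8, alpha = a0 * 2))
  fit_pi_curve(d, y ~ Ps * (1 - exp(-alpha * I / Ps)), starts, "platt_fit",
               function(I, p) p[["Ps"]] * (1 - exp(-p[["alpha"]] * I / p[["Ps"]])))
}

#' Fit the hyperbolic-tangent photosynthesis-irradiance curve
#'
#' Nonlinear least squares of `NPP = Ps * tanh(I / Ik) + DR` to net
#' photosynthesis measurements; `DR <= 0` is the dark respiration offset
#' (`NPP(0) = DR`).
#'
#' @param I irradiance, or a two-column data frame `(I, npp)`.
#' @param npp net photosynthesis.
#' @return object of class `c("chalker_fit", "pi_fit")` with coefficients
#'   `Ps`, `Ik`, `DR`.
#' @export
fit_chalker <- function(I, npp = NULL) {
  d <- if (is.data.frame(I)) stats::setNames(I[, 1:2], c("I", "y")) else
    data.frame(I = I, y = npp)
  dr0 <- min(min(d$y), 0)
  ps0 <- max(d$y) - dr0
  ik0 <- {
    half <- dr0 + 0.5 * ps0
    above <- d$I[d$y >= half]
    if (length(above)) max(min(above), 1) else max(d$I) / 4
  }
  starts <- list(list(Ps = ps0, Ik = ik0, DR = dr0),
                 list(Ps = ps0 * 1.3, Ik = ik0 * 2, DR = dr0 * 0.5 - 0.01),
                 list(Ps = ps0 * 0.9, Ik = ik0 * 0.5, DR = dr0 * 1.5 - 0.01))
  fit_pi_curve(d, y ~ Ps * tanh(I / Ik) + DR, starts, "chalker_fit",
               function(I, p) p[["Ps"]] * tanh(I / p[["Ik"]]) + p[["DR"]])
}

#' @export
print.pi_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  for (i in seq_along(est)) {
    cat(sprintf("  %-6s %12.6g  (SE %.3g)\n", names(est)[i], est[i], se[i]))
  }
  cat("  n = ", nrow(x$data), ", residual sigma = ",
      format(x$sigma, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.pi_fit <- function(object, ...) object$coefficients

#' @export
vcov.pi_fit <- function(object, ...) object$vcov

#' Predict a fitted photosynthesis-irradiance curve
#'
#' First-order (delta method) standard errors and confidence intervals are
#' propagated from the parameter covariance.
#'
#' @param object a fit from [fit_platt()] or [fit_chalker()].
#' @param newdata numeric irradiances, or a data frame with column `I`.
#' @param interval `"none"` or `"confidence"`.
#' @param level confidence level.
#' @param ... unused.
#' @return numeric vector of predictions, or a data frame `I`, `fit`, `se`,
#'   `lwr`, `upr` when an interval is requested.
#' @export
predict.pi_fit <- function(object, newdata, interval = c("none", "confidence"),
                           level = 0.95, ...) {
  interval <- match.arg(interval)
  I <- if (is.data.frame(newdata)) newdata$I else newdata
  if (any(I < 0)) stop("irradiance must be >= 0")
  p <- object$coefficients
  fit <- object$form(I, p)
  if (interval == "none") return(fit)
  ## numeric gradient wrt parameters
  G <- vapply(seq_along(p), function(j) {
    h <- max(abs(p[j]), 1e-4) * 1e-6
    pp <- p; pp[j] <- pp[j] + h
    pm <- p; pm[j] <- pm[j] - h
    (object$form(I, pp) - object$form(I, pm)) / (2 * h)
  }, numeric(length(I)))
  G <- matrix(G, nrow = length(I))
  se <- sqrt(pmax(rowSums((G %*% object$vcov) * G), 0))
  tq <- stats::qt(1 - (1 - level) / 2, df = max(object$df, 1))
  data.frame(I = I, fit = fit, se = se, lwr = fit - tq * se,
             upr = fit + tq * se)
}

#' Compensation irradiance from a tanh-form fit
#'
#' The irradiance at which net photosynthesis is zero:
#' `Ic = Ik * atanh(-DR / Ps)`, which requires `0 < -DR/Ps < 1`.
#'
#' @param fit a `chalker_fit`, or a named list/vector with `Ps`, `Ik`, `DR`.
#' @return Ic (umol photons m^-2 s^-1).
#' @export
compensation_irradiance <- function(fit) {
  p <- if (inherits(fit, "pi_fit")) as.list(fit$coefficients) else as.list(fit)
  ratio <- -p$DR / p$Ps
  if (ratio < 0) stop("DR must be <= 0")
  if (ratio >= 1) {
    stop("|DR| >= Ps: the curve never reaches compensation")
  }
  if (ratio == 0) return(0)
  p$Ik * atanh(ratio)
}

#' Closed-form upper bound on non-growth ATP maintenance
#'
#' At the compensation irradiance photosynthesis exactly covers
#' maintenance, so the photon flux absorbed there bounds the maintenance
#' ATP budget: `r_NGAM = Ic * a_chl * r * 3.6 * phi_m * e`. Unit chain:
#' irradiance (umol photons m^-2 s^-1) x chl-specific absorption
#' (m^2 (mg chl a)^-1) x chl a content (mg chl a gDW^-1) gives umol photons
#' gDW^-1 s^-1; the factor 3.6 converts to mmol photons gDW^-1 h^-1;
#' `phi_m` (mol O2 per mol photon) converts photons to O2 and `e` (mol ATP
#' per mol O2) converts O2 to ATP.
#'
#' @param Ic compensation irradiance (umol photons m^-2 s^-1), `>= 0`.
#' @param a_chl chlorophyll a specific absorption (m^2 (mg chl a)^-1).
#' @param r chlorophyll a to dry weight ratio (mg chl a gDW^-1).
#' @param phi_m quantum efficiency (mol O2 (mol photon)^-1).
#' @param e ATP generated per O2 (mol ATP (mol O2)^-1).
#' @return r_NGAM (mmol ATP gDW^-1 h^-1).
#' @export
ngam_upper_bound <- function(Ic, a_chl, r, phi_m, e) {
  args <- c(Ic = Ic, a_chl = a_chl, r = r, phi_m = phi_m, e = e)
  if (any(is.na(args))) {
    stop("missing factor(s): ", paste(names(args)[is.na(args)], collapse = ", "))
  }
  if (Ic < 0 || any(args[-1] < 0)) stop("all factors must be non-negative")
  Ic * a_chl * r * PHOTON_UNIT_BRIDGE * phi_m * e
}

#' Maintenance regression: ATP utilization against growth rate
#'
#' Ordinary least squares of optimal ATP hydrolysis (obtained by fixing
#' growth at each measured rate and maximizing the maintenance reaction)
#' against growth rate. The slope estimates growth-associated maintenance
#' (mmol ATP gDW^-1), the intercept non-growth-associated maintenance
#' (mmol ATP gDW^-1 h^-1).
#'
#' @param growth_rate measured growth rates (h^-1); at least 2 points.
#' @param atp_opt optimal ATP hydrolysis at each rate (mmol gDW^-1 h^-1).
#' @return list: `gam` (slope), `ngam` (intercept), `r_squared`,
#'   `se` (named, slope and intercept), and the underlying `lm` fit.
#' @export
gam_regression <- function(growth_rate, atp_opt) {
  if (length(growth_rate) < 2L) stop("need at least 2 points")
  fit <- stats::lm(atp_opt ~ growth_rate)
  ## exact lines are legitimate inputs; silence lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  list(gam = unname(stats::coef(fit)[2]),
       ngam = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       se = c(gam = sm$coefficients[2, 2], ngam = sm$coefficients[1, 2]),
       fit = fit)
}

#' Maximal ATP hydrolysis at a fixed growth rate
#'
#' Fixes the biomass demand at the measured growth rate and maximizes the
#' maintenance (ATP hydrolysis) reaction -- the per-condition input to
#' [gam_regression()].
#'
#' @param model a metabolic model.
#' @param growth_rate measured growth rate (h^-1).
#' @param growth_id biomass demand reaction id.
#' @param atpm_id maintenance reaction id.
#' @return optimal ATPM flux (mmol gDW^-1 h^-1), or `NA` if infeasible.
#' @export
max_atp_at_growth <- function(model, growth_rate, growth_id = "DM_biomass_c",
                              atpm_id = "ATPM") {
  m <- set_bounds(model, growth_id, growth_rate, growth_rate)
  sol <- solve_fba(m, objective = stats::setNames(1, atpm_id))
  if (sol$status == "optimal") sol$objective_value else NA_real_
}

#' Get or set the growth-associated maintenance of a biomass reaction
#'
#' The GAM appears in the biomass reaction as an ATP hydrolysis term
#' (`gam` mmol ATP per gDW of biomass formed). The current value is stored
#' on the reaction and adjusted in place.
#'
#' @param model a metabolic model built with [build_biomass_objective()]
#'   conventions (GAM over `atp_c`/`h2o_c`/`adp_c`/`pi_c`/`h_c`).
#' @param gam new GAM value (mmol ATP gDW^-1), `>= 0`.
#' @param biomass_id biomass reaction id.
#' @return `set_biomass_gam` returns the model; `get_biomass_gam` the value.
#' @export
set_biomass_gam <- function(model, gam, biomass_id = "BIOMASS") {
  stopifnot(gam >= 0)
  old <- get_biomass_gam(model, biomass_id)
  r <- model$reactions[[biomass_id]]
  d <- gam - old
  for (sp in c("atp_c", "h2o_c")) {
    r$stoichiometry[sp] <- (if (sp %in% names(r$stoichiometry))
      r$stoichiometry[[sp]] else 0) - d
  }
  for (sp in c("adp_c", "pi_c", "h_c")) {
    r$stoichiometry[sp] <- (if (sp %in% names(r$stoichiometry))
      r$stoichiometry[[sp]] else 0) + d
  }
  r$stoichiometry <- r$stoichiometry[abs(r$stoichiometry) > 1e-12]
  attr(r, "gam") <- gam
  model$reactions[[biomass_id]] <- r
  model
}

#' @rdname set_biomass_gam
#' @export
get_biomass_gam <- function(model, biomass_id = "BIOMASS") {
  r <- model$reactions[[biomass_id]]
  if (is.null(r)) stop("no biomass reaction: ", biomass_id)
  g <- attr(r, "gam")
  if (!is.null(g)) return(g)
  ## infer from the ATP coefficient net of non-GAM use (none by convention)
  if ("atp_c" %in% names(r$stoichiometry)) -r$stoichiometry[["atp_c"]] else 0
}

#' Calibrate growth-associated maintenance against a measured growth rate
#'
#' Bisection on the GAM coefficient embedded in the biomass reaction until
#' the model's optimal growth matches the measured rate within `tol`
#' (relative). Growth decreases monotonically in GAM, which the search
#' verifies as it brackets.
#'
#' @param model model with the condition constraints applied and the
#'   maintenance lower bound already set (see `ngam`).
#' @param measured_growth target growth rate (h^-1), `> 0`.
#' @param ngam non-growth maintenance set as the `ATPM` lower bound
#'   (mmol gDW^-1 h^-1).
#' @param tol relative tolerance on the growth match.
#' @param gam_max upper edge of the search bracket (mmol ATP gDW^-1).
#' @param biomass_id,atpm_id reaction ids.
#' @return list: `gam`, `growth` (achieved), `iterations`.
#' @export
calibrate_gam <- function(model, measured_growth, ngam = 0, tol = 1e-3,
                          gam_max = 20000, biomass_id = "BIOMASS",
                          atpm_id = "ATPM") {
  stopifnot(measured_growth > 0)
  model <- set_bounds(model, atpm_id, lower = ngam)
  growth_at <- function(g) {
    sol <- solve_fba(set_biomass_gam(model, g, biomass_id))
    if (sol$status != "optimal") 0 else sol$objective_value
  }
  g0 <- growth_at(0)
  if (g0 < measured_growth * (1 - tol)) {
    stop("measured growth ", measured_growth,
         " h^-1 is unattainable even at GAM = 0 (max feasible ",
         format(g0, digits = 6), " h^-1)")
  }
  lo <- 0; hi <- gam_max
  ghi <- growth_at(hi)
  if (ghi > measured_growth) {
    stop("growth still exceeds the target at GAM = ", gam_max,
         "; raise gam_max")
  }
  glo <- g0
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    gm <- growth_at(mid)
    if (abs(gm - measured_growth) <= tol * measured_growth || it >= 60L) {
      return(list(gam = mid, growth = gm, iterations = it))
    }
    if (gm > measured_growth) {
      ## more maintenance needed to slow growth to the target
      if (gm > glo + 1e-12) stop("growth is not monotone decreasing in GAM")
      lo <- mid; glo <- gm
    } else {
      hi <- mid; ghi <- gm
    }
  }
}
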