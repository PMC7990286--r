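## Dense bounded-variable linear programming core.
##
## Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
## with a two-phase primal simplex.  Artificial variables are kept in the
## working problem permanently (pinned to zero in phase 2), so rank-deficient
## constraint matrices -- routine for stoichiometric networks with conserved
## moieties -- never produce a singular basis.
##
## Problem sizes here are small (tens to a few hundred variables), so the
## basis system is re-solved densely at every iteration; robustness and
## determinism are worth far more than speed at this scale.

#' Solve a bounded-variable linear program
#'
#' Low-level solver used by [solve_fba()] and [solve_pfba()]. Maximizes (or
#' minimizes) `obj` over `A %*% x == b`, `lb <= x <= ub`.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n); may be row rank-deficient.
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize logical; if `FALSE` the objective is minimized.
#' @param tol numeric tolerance for optimality and feasibility tests.
#' @param max_iter iteration cap for each simplex phase.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution, length n) and `objval`.
#' @keywords internal
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-8,
                     max_iter = 50000L) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  }
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  if (is.null(A) || NROW(A) == 0L) {
    ## pure box problem
    x <- ifelse(cc > 0, ub, ifelse(cc < 0, lb, pmin(pmax(0, lb), ub)))
    if (any(!is.finite(x) & cc != 0)) {
      return(list(status = "unbounded", x = rep(NA_real_, n), objval = NA_real_))
    }
    x[!is.finite(x)] <- pmin(pmax(0, lb), ub)[!is.finite(x)]
    return(list(status = "optimal", x = x,
                objval = sum(obj * x)))
  }

  A <- as.matrix(A)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m)

  ## equilibrate: scale rows to unit max, then substitute v_j = cs_j u_j so
  ## columns also have unit max. Wide coefficient ranges (a maintenance
  ## coefficient of several thousand beside trace-pigment stoichiometry)
  ## otherwise degrade the basis condition number.
  rs <- apply(abs(A), 1, max)
  rs[rs < 1e-12] <- 1
  A <- A / rs
  b <- b / rs
  cs <- apply(abs(A), 2, max)
  cs[cs < 1e-12] <- 1
  A <- sweep(A, 2, cs, "/")
  lb <- lb * cs
  ub <- ub * cs
  cc <- cc / cs
  obj_scale <- cs

  ## start nonbasic structurals at the finite bound nearest zero
  start_val <- function(l, u) {
    if (is.finite(l) && l > 0) l
    else if (is.finite(u) && u < 0) u
    else if (is.finite(l) && is.finite(u) && abs(u) < abs(l)) u
    else if (is.finite(l)) max(l, min(u, 0))
    else if (is.finite(u)) min(u, 0)
    else 0
  }
  xv <- vapply(seq_len(n), function(j) start_val(lb[j], ub[j]), numeric(1))

  r0 <- as.numeric(b - A %*% xv)
  sgn <- ifelse(r0 >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  xall <- c(xv, abs(r0))
  basis <- n + seq_len(m)
  ntot <- n + m

  run_phase <- function(cvec, basis, xall, lbe, ube, bland = FALSE) {
    degen <- if (bland) 1000000L else 0L
    for (it in seq_len(max_iter)) {
      nonb <- setdiff(seq_len(ntot), basis)
      B <- Aext[, basis, drop = FALSE]
      xB <- tryCatch(
        solve(B, b - Aext[, nonb, drop = FALSE] %*% xall[nonb]),
        error = function(e) stop("LP basis became singular: ", conditionMessage(e))
      )
      xall[basis] <- as.numeric(xB)
      y <- solve(t(B), cvec[basis])
      d <- cvec[nonb] - as.numeric(crossprod(Aext[, nonb, drop = FALSE], y))

      at_lo <- abs(xall[nonb] - lbe[nonb]) < 1e-9 & is.finite(lbe[nonb])
      at_up <- abs(xall[nonb] - ube[nonb]) < 1e-9 & is.finite(ube[nonb])
      dir <- numeric(length(nonb))
      dir[at_lo & d > tol] <- 1
      dir[at_up & !at_lo & d < -tol] <- -1
      free <- !at_lo & !at_up
      dir[free & abs(d) > tol] <- sign(d[free & abs(d) > tol])
      dir[ube[nonb] - lbe[nonb] < 1e-12] <- 0       # fixed vars never enter
      cand <- which(dir != 0)
      if (!length(cand)) {
        return(list(status = "optimal", basis = basis, xall = xall))
      }
      pick <- if (degen > 4L * m + 20L) {
        cand[which.min(nonb[cand])]           # Bland's rule: anti-cycling
      } else {
        cand[which.max(abs(d[cand]))]
      }
      q <- nonb[pick]; dq <- dir[pick]

      w <- as.numeric(solve(B, Aext[, q]))
      ## ratio test
      tmax <- if (dq > 0) ube[q] - xall[q] else xall[q] - lbe[q]
      if (!is.finite(tmax)) tmax <- Inf
      ratios <- rep(Inf, m)
      if (dq > 0) {
        up <- w > 1e-10; dn <- w < -1e-10
        ratios[up] <- (xall[basis][up] - lbe[basis][up]) / w[up]
        ratios[dn] <- (ube[basis][dn] - xall[basis][dn]) / (-w[dn])
      } else {
        up <- w > 1e-10; dn <- w < -1e-10
        ratios[up] <- (ube[basis][up] - xall[basis][up]) / w[up]
        ratios[dn] <- (xall[basis][dn] - lbe[basis][dn]) / (-w[dn])
      }
      ratios[ratios < 0] <- 0
      rmin <- min(ratios)
      tstep <- min(rmin, tmax)
      if (!is.finite(tstep)) {
        return(list(status = "unbounded", basis = basis, xall = xall))
      }
      degen <- if (tstep < 1e-10) degen + 1L else 0L
      if (tmax <= rmin) {
        ## bound flip, basis unchanged
        xall[q] <- if (dq > 0) ube[q] else lbe[q]
      } else {
        ## widened (Harris-style) pivot window: among near-minimal ratios,
        ## prefer the largest pivot element for numerical stability
        hit <- which(ratios <= rmin + max(1e-9, 1e-7 * rmin))
        if (max(abs(w[hit])) < 1e-8) {
          hit <- which(ratios <= rmin * 1.001 + 1e-7)
        }
        r <- hit[which.max(abs(w[hit]))]
        leave <- basis[r]
        xall[q] <- xall[q] + dq * tstep
        ## leaving variable goes to the bound it hit
        lv <- if (dq > 0) {
          if (w[r] > 0) lbe[leave] else ube[leave]
        } else {
          if (w[r] > 0) ube[leave] else lbe[leave]
        }
        xall[leave] <- lv
        basis[r] <- q
      }
    }
    stop("LP iteration limit reached (", max_iter, ")")
  }

  solve_both_phases <- function(bland) {
    c1 <- c(rep(0, n), rep(-1, m))
    ph1 <- run_phase(c1, basis, xall, lbe, ube, bland = bland)
    if (ph1$status != "optimal") {
      stop("internal error: phase-1 LP reported ", ph1$status)
    }
    infeas <- sum(ph1$xall[n + seq_len(m)])
    if (infeas > sqrt(tol)) {
      return(list(status = "infeasible", x = rep(NA_real_, n),
                  objval = NA_real_))
    }
    ## pin artificials at zero for phase 2
    ube2 <- ube
    ube2[n + seq_len(m)] <- 0
    x1 <- ph1$xall
    x1[n + seq_len(m)] <- 0
    c2 <- c(cc, rep(0, m))
    ph2 <- run_phase(c2, ph1$basis, x1, lbe, ube2, bland = bland)
    if (ph2$status == "unbounded") {
      return(list(status = "unbounded", x = rep(NA_real_, n),
                  objval = NA_real_))
    }
    x <- ph2$xall[seq_len(n)]
    x <- pmin(pmax(x, lb), ub)   # snap to bounds within tolerance
    x <- x / obj_scale           # undo column equilibration
    list(status = "optimal", x = x, objval = sum(obj * x))
  }
  ## a numerically singular basis can appear under aggressive (Dantzig)
  ## pivoting on near-degenerate problems; retry once with Bland's rule,
  ## whose conservative pivots take a more stable path
  tryCatch(solve_both_phases(bland = FALSE),
           error = function(e) {
             if (grepl("singular", conditionMessage(e))) {
               solve_both_phases(bland = TRUE)
             } else stop(e)
           })
}
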