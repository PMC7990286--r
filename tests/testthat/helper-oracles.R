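## Independent oracles and tiny fixture networks used across the suite.

## Brute-force FBA oracle for small networks with all-finite bounds:
## enumerates every vertex of {S v = 0, lb <= v <= ub} by choosing basic
## columns over a full-row-rank subset of S and placing the remaining
## variables at each bound combination. Independent of the simplex path.
enum_fba_optimum <- function(model, objective = model$objective) {
  S <- stoich_matrix(model)
  bd <- get_bounds(model)
  lb <- bd$lower; ub <- bd$upper
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  obj <- stats::setNames(numeric(ncol(S)), colnames(S))
  obj[names(objective)] <- objective
  ## reduce to independent rows
  qrS <- qr(t(S))
  keep <- qrS$pivot[seq_len(qrS$rank)]
  A <- S[keep, , drop = FALSE]
  r <- nrow(A); n <- ncol(A)
  best <- -Inf; feasible <- FALSE; best_x <- NULL; all_opt <- list()
  combs <- utils::combn(n, r)
  for (k in seq_len(ncol(combs))) {
    bas <- combs[, k]
    B <- A[, bas, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nonb <- setdiff(seq_len(n), bas)
    grid <- expand.grid(rep(list(1:2), length(nonb)))
    if (!length(nonb)) grid <- data.frame(row.names = 1)
    for (g in seq_len(max(nrow(grid), 1))) {
      xn <- if (length(nonb)) {
        ifelse(unlist(grid[g, ]) == 1, lb[nonb], ub[nonb])
      } else numeric(0)
      xb <- solve(B, -(if (length(nonb)) A[, nonb, drop = FALSE] %*% xn
                       else rep(0, r)))
      x <- numeric(n); x[bas] <- xb; x[nonb] <- xn
      if (all(x >= lb - 1e-8) && all(x <= ub + 1e-8) &&
          max(abs(S %*% x)) < 1e-8) {
        feasible <- TRUE
        val <- sum(obj * x)
        if (val > best + 1e-9) {
          best <- val; best_x <- x; all_opt <- list(x)
        } else if (abs(val - best) <= 1e-9) {
          all_opt <- c(all_opt, list(x))
        }
      }
    }
  }
  list(feasible = feasible, optimum = best,
       x = stats::setNames(best_x, colnames(S)),
       vertices_at_optimum = lapply(all_opt, stats::setNames, colnames(S)))
}

## linear chain EX_A -> A -> B -> EX_B, all bounds [0, 10]
chain_model <- function(ub = 10) {
  metabolic_model(
    list(metabolite("A", formula = "C", compartment = "c"),
         metabolite("B", formula = "C", compartment = "c")),
    list(reaction("EX_A", c(A = 1), 0, ub),      # uptake written as inflow
         reaction("R1", c(A = -1, B = 1), 0, ub),
         reaction("EX_B", c(B = -1), 0, ub)),
    objective = c(EX_B = 1), id = "chain")
}

## two routes from A to B: direct (yield 1) and two-step via C
parallel_model <- function() {
  metabolic_model(
    list(metabolite("A", compartment = "c"),
         metabolite("B", compartment = "c"),
         metabolite("C", compartment = "c")),
    list(reaction("EX_A", c(A = 1), 0, 5),
         reaction("direct", c(A = -1, B = 1), 0, 10),
         reaction("via1", c(A = -1, C = 1), 0, 10),
         reaction("via2", c(C = -1, B = 1), 0, 10),
         reaction("EX_B", c(B = -1), 0, 10)),
    objective = c(EX_B = 1), id = "parallel")
}

## a reversible 3-cycle disconnected from the producing path
loop_model <- function() {
  metabolic_model(
    list(metabolite("A", compartment = "c"),
         metabolite("X", compartment = "c"),
         metabolite("Y", compartment = "c"),
         metabolite("Z", compartment = "c")),
    list(reaction("EX_A", c(A = 1), 0, 10),
         reaction("R1", c(A = -1), 0, 10),
         reaction("L1", c(X = -1, Y = 1), -10, 10),
         reaction("L2", c(Y = -1, Z = 1), -10, 10),
         reaction("L3", c(Z = -1, X = 1), -10, 10)),
    objective = c(R1 = 1), id = "loop")
}

## cached expensive fixtures, shared across test files within one run
.cache <- new.env(parent = emptyenv())
cached_toy_model <- function() {
  if (is.null(.cache$toy)) .cache$toy <- make_toy_phototroph_model()
  .cache$toy
}
cached_batch_run <- function() {
  if (is.null(.cache$batch)) {
    m <- cached_toy_model()
    tg <- make_batch_timeseries(seed = 7)
    .cache$batch <- run_dfba(m, tg)
  }
  .cache$batch
}

## electron content relative to CO2 / H2O / NH3 / H2S / HPO4 / Si(OH)4:
## a conserved quantity of every mass- and charge-balanced reaction
e_content <- function(formula, charge = 0) {
  ct <- parse_formula(formula)
  gx <- function(el) if (el %in% names(ct)) ct[[el]] else 0
  4 * gx("C") + gx("H") - 2 * gx("O") - 3 * gx("N") - 2 * gx("S") +
    5 * gx("P") + 4 * gx("Si") + 2 * gx("Mg") - charge
}
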