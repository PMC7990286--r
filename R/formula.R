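## Elemental formula utilities shared by the balance checker, biomass
## construction, degree-of-reduction and photosynthetic-quotient code.

.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Si = 28.085, Mg = 24.305, Fe = 55.845, K = 39.098, Na = 22.99,
  Ca = 40.078, Cl = 35.45, Zn = 65.38, Mn = 54.938, Co = 58.933
)

#' Parse an elemental formula string
#'
#' Turns `"C6H12O6"` (or `"SiO2.5H1"`, fractional counts are allowed for
#' lumped species) into a named numeric vector of atom counts. An empty
#' string parses to an empty vector (a massless bookkeeping species such as
#' a photon or an excitation state).
#'
#' @param x formula string.
#' @return named numeric vector, names are element symbols.
#' @export
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("SiO2.5H1")
parse_formula <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(x)) {
    stop("cannot parse formula: '", x, "'")
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  ct <- sub("^[A-Z][a-z]?", "", toks)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  out <- tapply(ct, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Format an atom-count vector as a formula string
#' @param counts named numeric vector of atom counts.
#' @return character formula, Hill-ish ordering (C, H, then alphabetical).
#' @export
format_formula <- function(counts) {
  counts <- counts[abs(counts) > 1e-12]
  if (!length(counts)) return("")
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  counts <- counts[ord]
  fmt1 <- function(v) {
    if (abs(v - round(v)) < 1e-9) {
      if (round(v) == 1) "" else as.character(round(v))
    } else as.character(signif(v, 6))
  }
  paste0(names(counts), vapply(counts, fmt1, character(1)), collapse = "")
}

#' Molar mass of a formula
#' @param x formula string or named atom-count vector.
#' @return molar mass in g/mol.
#' @export
molar_mass <- function(x) {
  counts <- if (is.character(x)) parse_formula(x) else x
  if (!length(counts)) return(0)
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown)) stop("no atomic weight for element(s): ",
                            paste(unknown, collapse = ", "))
  sum(counts * .atomic_weights[names(counts)])
}

## add/scale atom-count vectors
formula_add <- function(a, b, w = 1) {
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + w * b
  out[abs(out) > 1e-12]
}
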