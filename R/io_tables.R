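## Delimited-text interfaces for the tabular inputs: pigment spectra and
## composition tables, light-source spectra, and P-I curve tables. The
## copies under inst/extdata are editable starting points generated from
## the package defaults.

#' Write and read pigment profiles as delimited text
#'
#' The on-disk layout is long-form TSV with columns `pigment`, `bin_nm`,
#' `value` for the spectra, plus per-pigment rows (`bin_nm = NA`) holding
#' the mass fraction (`quantity = "mass_fraction"`) and transfer
#' efficiency (`quantity = "transfer_efficiency"`).
#'
#' @param profile a [pigment_profile()].
#' @param path TSV path.
#' @return `write_pigment_profile` returns `path` invisibly;
#'   `read_pigment_profile` returns a [pigment_profile()].
#' @export
write_pigment_profile <- function(profile, path) {
  stopifnot(inherits(profile, "pigment_profile"))
  sp <- profile$spectra
  long <- data.frame(
    pigment = rep(rownames(sp), ncol(sp)),
    quantity = "absorption_m2_per_g",
    bin_nm = rep(as.integer(colnames(sp)), each = nrow(sp)),
    value = as.numeric(sp))
  extras <- rbind(
    data.frame(pigment = names(profile$mass_fractions),
               quantity = "mass_fraction", bin_nm = NA_integer_,
               value = as.numeric(profile$mass_fractions)),
    data.frame(pigment = names(profile$transfer_efficiency),
               quantity = "transfer_efficiency", bin_nm = NA_integer_,
               value = as.numeric(profile$transfer_efficiency)))
  utils::write.table(rbind(long, extras), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pigment_profile
#' @export
read_pigment_profile <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  sp_rows <- d[d$quantity == "absorption_m2_per_g", ]
  pigs <- unique(sp_rows$pigment)
  sp <- matrix(0, length(pigs), length(par_bins()),
               dimnames = list(pigs, as.character(par_bins())))
  for (i in seq_len(nrow(sp_rows))) {
    sp[sp_rows$pigment[i], as.character(sp_rows$bin_nm[i])] <-
      sp_rows$value[i]
  }
  mf <- d[d$quantity == "mass_fraction", ]
  te <- d[d$quantity == "transfer_efficiency", ]
  pigment_profile(stats::setNames(mf$value, mf$pigment), sp,
                  stats::setNames(te$value, te$pigment))
}

#' Write and read a light-source spectrum as delimited text
#' @param source named numeric of per-bin photon-flux fractions.
#' @param path TSV path (columns `bin_nm`, `fraction`).
#' @export
write_light_source <- function(source, path) {
  utils::write.table(
    data.frame(bin_nm = as.integer(names(source)),
               fraction = as.numeric(source)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_light_source
#' @export
read_light_source <- function(path) {
  d <- utils::read.delim(path)
  stats::setNames(d$fraction, as.character(d$bin_nm))
}

#' Write a photosynthesis-irradiance table as delimited text
#' @param curves data frame with at least `I` and a rate column (plus
#'   optional `condition`, `replicate`), as produced by
#'   [make_chemostat_dataset()].
#' @param path TSV path.
#' @export
write_pi_table <- function(curves, path) {
  utils::write.table(curves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pi_table
#' @export
read_pi_table <- function(path) utils::read.delim(path)
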