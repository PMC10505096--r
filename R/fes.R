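#' Free-energy profile along the membrane normal by Boltzmann inversion
#'
#' Bins the z-positions of all solute copies (after an optional
#' equilibration skip) into a probability density `P(z)` and inverts it to a
#' free-energy profile `F(z) = -ln P(z)` in units of kT, gauge-fixed so the
#' lowest occupied bin is zero. Unoccupied bins carry `NA` ("unsampled"),
#' never a number: no free-energy value is invented where there is no
#' sampling. `F` is invariant to the number of samples (duplicating the data
#' leaves it unchanged) and equivariant under translation of z.
#'
#' @param series A recentred [zseries()].
#' @param bin_width Histogram bin width (nm, default 0.1). Bin edges are
#'   aligned so that z = 0 is an edge.
#' @param equilibration_skip Discard frames with `time < equilibration_skip`
#'   (ns, default 0).
#' @param symmetrize Average the profile across z = 0 (default `FALSE`; use
#'   for compositionally symmetric membranes).
#' @return Object of class `fes_profile`: list with `bin_centers` (nm),
#'   `probability` (density, 1/nm; sums to 1 when multiplied by
#'   `bin_width`), `free_energy` (kT; `NA` on unsampled bins), `occupied`
#'   (logical), `temperature` (K), `bin_width` (nm), `n_samples`.
#' @examples
#' zs <- zseries(1:1000, runif(1000, -6, 6), box_z = 12, temperature = 440)
#' fp <- compute_fes(zs, bin_width = 0.5)
#' range(fp$free_energy[fp$occupied])
#' @export
compute_fes <- function(series, bin_width = 0.1, equilibration_skip = 0,
                        symmetrize = FALSE) {
  stopifnot(inherits(series, "zseries"))
  if (bin_width <= 0) pc_input_error("bin_width must be positive")
  keep <- series$times >= equilibration_skip
  if (!any(keep))
    pc_stop("equilibration_skip discards every frame", "permcount_empty_data")
  zz <- as.numeric(series$z[keep, , drop = FALSE])
  half <- max(series$box_z) / 2
  nb <- ceiling(half / bin_width)
  edges <- seq(-nb, nb) * bin_width
  idx <- findInterval(zz, edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx <= 2L * nb]
  counts <- tabulate(idx, nbins = 2L * nb)
  if (symmetrize) counts <- (counts + rev(counts)) / 2
  n <- sum(counts)
  prob <- counts / (n * bin_width)
  occ <- counts > 0
  fe <- rep(NA_real_, length(prob))
  fe[occ] <- -log(prob[occ])
  fe <- fe - min(fe, na.rm = TRUE)
  structure(
    list(bin_centers = (edges[-1L] + edges[-length(edges)]) / 2,
         probability = prob, free_energy = fe, occupied = occ,
         temperature = series$temperature, bin_width = bin_width,
         n_samples = length(zz)),
    class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat(sprintf(
    paste0("fes_profile: %d bins of %.3g nm, %d samples, T = %.6g K\n",
           "  occupied %d bins; max F = %.3g kT (%.3g kJ/mol)\n"),
    length(x$bin_centers), x$bin_width, x$n_samples, x$temperature,
    sum(x$occupied), max(x$free_energy, na.rm = TRUE),
    max(fes_energy_kJmol(x), na.rm = TRUE)))
  invisible(x)
}

#' Free energy of a profile in kJ/mol
#'
#' Converts the kT-unit profile to kJ/mol using the profile's own
#' temperature: `F * k_B * N_A * T / 1000`.
#'
#' @param profile A [compute_fes()] result.
#' @return Numeric vector (kJ/mol, `NA` on unsampled bins).
#' @export
fes_energy_kJmol <- function(profile) {
  stopifnot(inherits(profile, "fes_profile"))
  profile$free_energy * .BOLTZMANN * .AVOGADRO * profile$temperature / 1000
}

#' Export a free-energy profile as TSV
#'
#' Columns `z_nm`, `P`, `F_kT`; unsampled bins carry `NA` in `F_kT`.
#'
#' @param profile A [compute_fes()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fes_tsv <- function(profile, path) {
  df <- data.frame(z_nm = profile$bin_centers, P = profile$probability,
                   F_kT = profile$free_energy)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
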