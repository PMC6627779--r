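#' Mean residue ellipticity
#'
#' Converts a measured ellipticity in millidegrees to mean residue
#' ellipticity, `[theta] = theta / (10 * [P] * l * n)` in
#' deg cm^2 / dmol, where `[P]` is the molar protein concentration, `l` the
#' path length in cm and `n` the number of residues. The conversion is
#' linear in `theta`, so it maps whole spectra elementwise; buffer-blank
#' subtraction is assumed done upstream. `n` is taken as the residue count
#' (not peptide bonds).
#'
#' @param theta Ellipticity (mdeg), vectorised over a wavelength series.
#' @param protein_conc Protein concentration (mol/L), > 0.
#' @param path_length Cell path length (cm), > 0.
#' @param n_residues Number of amino-acid residues, >= 1.
#' @return Mean residue ellipticity (deg cm^2 / dmol), same shape as `theta`.
#' @export
mean_residue_ellipticity <- function(theta, protein_conc, path_length,
                                     n_residues) {
  check_numeric_vector(theta, "theta")
  check_positive(protein_conc, "protein_conc")
  check_positive(path_length, "path_length")
  check_number(n_residues, "n_residues", lower = 1)
  theta / (10 * protein_conc * path_length * n_residues)
}
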