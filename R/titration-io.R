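#' Construct a titration series
#'
#' A `titration_series` holds one fluorescence quenching titration performed at
#' fixed protein concentration and temperature: the total ligand concentration
#' grid, the fluorescence intensity at the analysis wavelength at each step
#' (the intensity at zero ligand is F0), and optionally the absorbances at the
#' excitation and emission wavelengths used for inner-filter correction.
#'
#' All concentrations are in mol/L and temperatures in K. Conversion from
#' other units happens at the file boundary (see [read_titration_table()]).
#'
#' @param ligand_total Numeric vector of total ligand concentrations (mol/L),
#'   non-decreasing. A first entry of 0 supplies F0.
#' @param intensity Positive numeric vector of fluorescence intensities
#'   (arbitrary units), same length as `ligand_total`.
#' @param protein_conc Total protein concentration (mol/L), > 0.
#' @param temperature Temperature (K), > 0.
#' @param absorbance_ex,absorbance_em Optional non-negative absorbance vectors
#'   at the excitation and emission wavelengths (unitless), same length as
#'   `ligand_total`. When both are supplied intensities are inner-filter
#'   corrected on construction (see [correct_inner_filter()]) and
#'   `inner_filter_corrected` is set.
#' @param added_volume Optional cumulative added titrant volume (L) per point,
#'   used only when `dilution_correction = TRUE`.
#' @param dilution_correction Logical; correct intensities and concentrations
#'   for titrant dilution using `added_volume` and `sample_volume`. Default
#'   `FALSE`: small-aliquot titrations are conventionally analysed without
#'   dilution correction.
#' @param sample_volume Initial sample volume (L); required when
#'   `dilution_correction = TRUE`.
#'
#' @return An object of class `titration_series`: a list with the validated
#'   fields plus `inner_filter_corrected` (logical flag recording whether
#'   correction was applied at load time).
#' @export
titration_series <- function(ligand_total, intensity, protein_conc,
                             temperature, absorbance_ex = NULL,
                             absorbance_em = NULL, added_volume = NULL,
                             dilution_correction = FALSE,
                             sample_volume = NULL) {
  check_numeric_vector(ligand_total, "ligand_total", non_negative = TRUE)
  check_numeric_vector(intensity, "intensity", positive = TRUE)
  check_positive(protein_conc, "protein_conc")
  check_positive(temperature, "temperature")
  n <- length(ligand_total)
  if (length(intensity) != n) {
    stop_validation("ligand_total and intensity must have equal length")
  }
  if (any(diff(ligand_total) < 0)) {
    stop_validation("ligand_total must be non-decreasing")
  }

  corrected <- FALSE
  if (!is.null(absorbance_ex) || !is.null(absorbance_em)) {
    if (is.null(absorbance_ex) || is.null(absorbance_em)) {
      stop_validation("absorbance_ex and absorbance_em must be given together")
    }
    check_numeric_vector(absorbance_ex, "absorbance_ex", non_negative = TRUE)
    check_numeric_vector(absorbance_em, "absorbance_em", non_negative = TRUE)
    if (length(absorbance_ex) != n || length(absorbance_em) != n) {
      stop_validation("absorbance vectors must match ligand_total in length")
    }
    intensity <- correct_inner_filter(intensity, absorbance_ex, absorbance_em)
    corrected <- TRUE
  }

  if (isTRUE(dilution_correction)) {
    if (is.null(added_volume) || is.null(sample_volume)) {
      stop_validation(
        "dilution_correction requires added_volume and sample_volume")
    }
    check_numeric_vector(added_volume, "added_volume", non_negative = TRUE)
    check_positive(sample_volume, "sample_volume")
    if (length(added_volume) != n) {
      stop_validation("added_volume must match ligand_total in length")
    }
    dil <- (sample_volume + added_volume) / sample_volume
    intensity <- intensity * dil
    # total concentrations quoted per final volume are scaled back up
    ligand_total <- ligand_total * dil
  }

  structure(
    list(
      ligand_total = as.numeric(ligand_total),
      intensity = as.numeric(intensity),
      protein_conc = as.numeric(protein_conc),
      temperature = as.numeric(temperature),
      absorbance_ex = if (corrected) as.numeric(absorbance_ex) else NULL,
      absorbance_em = if (corrected) as.numeric(absorbance_em) else NULL,
      added_volume = if (!is.null(added_volume)) as.numeric(added_volume) else NULL,
      inner_filter_corrected = corrected
    ),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %d points, [P] = %.3g M, T = %.1f K%s\n",
    length(x$ligand_total), x$protein_conc, x$temperature,
    if (x$inner_filter_corrected) ", inner-filter corrected" else ""))
  invisible(x)
}

#' Construct an emission spectrum
#'
#' Container for one steady-state emission scan at fixed temperature and
#' excitation wavelength.
#'
#' @param wavelengths Strictly increasing numeric vector (nm).
#' @param intensities Non-negative numeric vector, same length.
#' @param temperature Temperature (K).
#' @param excitation_wavelength Excitation wavelength (nm).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, temperature,
                              excitation_wavelength) {
  check_numeric_vector(wavelengths, "wavelengths")
  check_numeric_vector(intensities, "intensities", non_negative = TRUE)
  if (!is_strictly_increasing(wavelengths)) {
    stop_validation("wavelengths must be strictly increasing")
  }
  if (length(wavelengths) != length(intensities)) {
    stop_validation("wavelengths and intensities must have equal length")
  }
  check_positive(temperature, "temperature")
  check_positive(excitation_wavelength, "excitation_wavelength")
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 temperature = temperature,
                 excitation_wavelength = excitation_wavelength),
            class = "emission_spectrum")
}

#' Inner-filter correction of observed fluorescence
#'
#' Corrects observed intensities for attenuation of the excitation beam and
#' re-absorption of the emitted light by the sample:
#' `F_corr = F_obs * 10^((A_ex + A_em) / 2)`, where `A_ex` and `A_em` are the
#' absorbances at the excitation and emission wavelengths. The correction is
#' the identity exactly when `A_ex + A_em = 0` and is monotone increasing in
#' each absorbance, so `F_corr >= F_obs` always.
#'
#' @param f_obs Observed fluorescence intensity (vectorised).
#' @param a_ex,a_em Non-negative absorbances (unitless), recycled to `f_obs`.
#' @return Corrected intensity, same shape as `f_obs`.
#' @export
correct_inner_filter <- function(f_obs, a_ex, a_em) {
  check_numeric_vector(f_obs, "f_obs")
  check_numeric_vector(a_ex, "a_ex", non_negative = TRUE)
  check_numeric_vector(a_em, "a_em", non_negative = TRUE)
  f_obs * 10^((a_ex + a_em) / 2)
}

#' Fluorescence quenching percentage
#'
#' The fractional signal change used by the interaction-density-function
#' analysis: `dF = |F - F0| / F0 * 100`. For quenching (`0 <= F <= F0`) the
#' result lies in \[0, 100\].
#'
#' @param f0 Intensity in the absence of ligand (> 0).
#' @param f Intensity in the presence of ligand (vectorised).
#' @return Quench percentage(s).
#' @export
quench_percent <- function(f0, f) {
  check_positive(f0, "f0")
  check_numeric_vector(f, "f")
  abs(f - f0) / f0 * 100
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' `c = A / (epsilon * l)` with `A` the absorbance, `epsilon` the molar
#' extinction coefficient (1/(M cm)) and `l` the path length (cm).
#'
#' @param absorbance Non-negative absorbance (unitless, vectorised).
#' @param epsilon Extinction coefficient, > 0 (1/(M cm)).
#' @param path_length Optical path length, > 0 (cm).
#' @return Concentration in mol/L.
#' @export
concentration_from_absorbance <- function(absorbance, epsilon,
                                          path_length = 1) {
  check_numeric_vector(absorbance, "absorbance", non_negative = TRUE)
  check_positive(epsilon, "epsilon")
  check_positive(path_length, "path_length")
  absorbance / (epsilon * path_length)
}

.conc_scale <- function(unit) {
  switch(tolower(unit),
    "m" = 1, "mol/l" = 1,
    "mm" = 1e-3,
    "um" = 1e-6, "µm" = 1e-6, "micromolar" = 1e-6,
    "nm" = 1e-9,
    stop_schema("unknown concentration unit: ", unit))
}

#' Read a titration table from CSV
#'
#' Reads a comma-separated titration table with `#`-prefixed metadata header
#' lines of the form `# key=value` (`protein_conc`, `temperature`, `units`).
#' Required columns are `ligand_total` and `intensity`; optional columns
#' `a_ex`, `a_em` (absorbances) and `added_volume`. Column names may be
#' remapped through `dialect`, and concentration units declared either in the
#' header (`units=uM`) or in `dialect$units` are converted to mol/L on read.
#'
#' @param path Path to the CSV file.
#' @param dialect Optional named list remapping this package's column names to
#'   the file's (e.g. `list(ligand_total = "L", intensity = "F")`) and/or
#'   overriding metadata: entries `units`, `protein_conc`, `temperature` take
#'   precedence over the file header.
#' @param ... Passed on to [titration_series()] (e.g. dilution correction).
#' @return A [titration_series()].
#' @export
read_titration_table <- function(path, dialect = list(), ...) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      meta[[key]] <- val
    }
  }
  tab <- utils::read.csv(text = lines[!grepl("^\\s*#", lines)],
                         stringsAsFactors = FALSE)

  colmap <- list(ligand_total = "ligand_total", intensity = "intensity",
                 a_ex = "a_ex", a_em = "a_em", added_volume = "added_volume")
  for (k in intersect(names(dialect), names(colmap))) colmap[[k]] <- dialect[[k]]

  get_col <- function(internal, required = FALSE) {
    nm <- colmap[[internal]]
    if (!nm %in% names(tab)) {
      if (required) stop_schema("missing required column: ", nm)
      return(NULL)
    }
    as.numeric(tab[[nm]])
  }

  units <- dialect$units %||% meta$units %||% "M"
  scale <- .conc_scale(units)

  protein_conc <- as.numeric(dialect$protein_conc %||% meta$protein_conc %||%
                               NA_real_)
  temperature <- as.numeric(dialect$temperature %||% meta$temperature %||%
                              NA_real_)
  if (is.na(protein_conc)) {
    stop_schema("protein_conc not found in header comments or dialect")
  }
  if (is.na(temperature)) {
    stop_schema("temperature not found in header comments or dialect")
  }

  lig <- get_col("ligand_total", required = TRUE) * scale
  if (any(diff(lig) < 0)) {
    stop_validation("ligand_total column is not non-decreasing")
  }
  already_corrected <- identical(tolower(meta$inner_filter_corrected %||% "false"),
                                 "true")
  if (already_corrected) {
    # intensities in the file are post-correction; absorbance columns are
    # provenance only and must not trigger a second correction
    out <- titration_series(
      ligand_total = lig,
      intensity = get_col("intensity", required = TRUE),
      protein_conc = protein_conc * scale,
      temperature = temperature,
      added_volume = get_col("added_volume"),
      ...
    )
    out$absorbance_ex <- get_col("a_ex")
    out$absorbance_em <- get_col("a_em")
    out$inner_filter_corrected <- TRUE
    return(out)
  }
  titration_series(
    ligand_total = lig,
    intensity = get_col("intensity", required = TRUE),
    protein_conc = protein_conc * scale,
    temperature = temperature,
    absorbance_ex = get_col("a_ex"),
    absorbance_em = get_col("a_em"),
    added_volume = get_col("added_volume"),
    ...
  )
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration_table()]: writes metadata as `# key=value`
#' header lines followed by the data columns, always in mol/L and K
#' (`units=M` is written explicitly). The written intensities are the series'
#' working intensities: if absorbances were supplied at construction the
#' stored intensities are already inner-filter corrected, the absorbance
#' columns are retained for provenance, and the header flag
#' `inner_filter_corrected=true` tells [read_titration_table()] not to
#' correct a second time.
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  hdr <- c(
    sprintf("# protein_conc=%.17g", series$protein_conc),
    sprintf("# temperature=%.17g", series$temperature),
    "# units=M",
    sprintf("# inner_filter_corrected=%s",
            tolower(series$inner_filter_corrected))
  )
  df <- data.frame(ligand_total = series$ligand_total,
                   intensity = series$intensity)
  if (!is.null(series$absorbance_ex)) {
    df$a_ex <- series$absorbance_ex
    df$a_em <- series$absorbance_em
  }
  if (!is.null(series$added_volume)) df$added_volume <- series$added_volume
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(df[i, ], function(v) sprintf("%.17g", v), character(1)),
          collapse = ",")
  }, character(1))
  writeLines(c(hdr, paste(names(df), collapse = ","), body), path)
  invisible(path)
}

#' Read a TCSPC decay trace from CSV
#'
#' Expects columns `time_ns` and `counts`.
#'
#' @param path Path to the CSV file.
#' @return A [decay_trace()].
#' @export
read_decay_table <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#")
  for (col in c("time_ns", "counts")) {
    if (!col %in% names(tab)) stop_schema("missing required column: ", col)
  }
  decay_trace(time = tab$time_ns, counts = tab$counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
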