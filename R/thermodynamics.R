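# Gas constants: SI for van't Hoff / Gibbs work, kcal-based for docking
# scores quoted in kcal/mol.
.R_SI <- 8.314       # J/(mol K)
.R_KCAL <- 1.987e-3  # kcal/(mol K)

#' Van't Hoff regression
#'
#' Fits `ln(Ka) = -dH/(R*T) + dS/R` by OLS of `ln(Ka)` against `1/T`, giving
#' the binding enthalpy `dH = -R * slope` and entropy `dS = R * intercept`
#' under the usual assumption that both are temperature-independent over the
#' measured range (no heat-capacity term).
#'
#' @param temperatures Numeric vector of temperatures (K), at least two
#'   distinct values.
#' @param ka_values Positive binding constants (1/M), same length.
#' @return An object of class `vant_hoff_fit`: list with `delta_h` (J/mol),
#'   `delta_s` (J/(mol K)), `delta_h_stderr`, `delta_s_stderr`, `r_squared`,
#'   `gas_constant`, `temperatures`, `ka_values`.
#' @export
vant_hoff_fit <- function(temperatures, ka_values) {
  check_numeric_vector(temperatures, "temperatures", min_len = 2L,
                       positive = TRUE)
  check_numeric_vector(ka_values, "ka_values", min_len = 2L, positive = TRUE)
  if (length(temperatures) != length(ka_values)) {
    stop_validation("temperatures and ka_values must have equal length")
  }
  if (length(unique(temperatures)) < 2L) {
    stop_validation("at least 2 distinct temperatures required")
  }
  x <- 1 / temperatures
  y <- log(ka_values)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  se <- if (length(temperatures) > 2L) sm$coefficients[, 2] else c(NA_real_, NA_real_)
  structure(
    list(
      delta_h = -.R_SI * unname(stats::coef(fit)[2]),
      delta_s = .R_SI * unname(stats::coef(fit)[1]),
      delta_h_stderr = .R_SI * unname(se[2]),
      delta_s_stderr = .R_SI * unname(se[1]),
      r_squared = sm$r.squared,
      gas_constant = .R_SI,
      temperatures = temperatures,
      ka_values = ka_values
    ),
    class = "vant_hoff_fit"
  )
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf(
    "<vant_hoff_fit> dH = %.2f kJ/mol, dS = %.2f J/(mol K), r2 = %.4f (%d temperatures)\n",
    x$delta_h / 1000, x$delta_s, x$r_squared, length(x$temperatures)))
  invisible(x)
}

#' Gibbs free energy from a van't Hoff fit
#'
#' `dG = dH - T*dS`, together with the entropic term `T*dS`. Uncertainty is
#' propagated from the fit's standard errors treating `dH` and `dS` as
#' independent.
#'
#' @param fit A [vant_hoff_fit()], or a list with `delta_h` and `delta_s`
#'   (J/mol and J/(mol K)).
#' @param temperature Temperature (K), > 0 (vectorised).
#' @return A data.frame with one row per temperature: `temperature`,
#'   `delta_g` (J/mol), `t_delta_s` (J/mol), `delta_g_stderr` (NA when the
#'   fit carries no standard errors).
#' @export
gibbs_free_energy <- function(fit, temperature) {
  check_numeric_vector(temperature, "temperature", positive = TRUE)
  dh <- fit$delta_h
  ds <- fit$delta_s
  check_number(dh, "delta_h")
  check_number(ds, "delta_s")
  se <- if (!is.null(fit$delta_h_stderr) && !is.na(fit$delta_h_stderr)) {
    sqrt(fit$delta_h_stderr^2 + (temperature * fit$delta_s_stderr)^2)
  } else {
    rep(NA_real_, length(temperature))
  }
  data.frame(
    temperature = temperature,
    delta_g = dh - temperature * ds,
    t_delta_s = temperature * ds,
    delta_g_stderr = se
  )
}

#' Binding constant from a docking score
#'
#' Converts a docking energy score (kcal/mol) to an equilibrium binding
#' constant via `Kb = exp(-dG / (R*T))` with `R = 1.987e-3 kcal/(mol K)`.
#' The default temperature of 300 K matches the thermostat temperature
#' conventionally used in the simulations the scores come from.
#'
#' @param delta_g Docking score (kcal/mol, vectorised; negative = favourable).
#' @param temperature Temperature (K). Default 300.
#' @return Binding constant(s) in 1/M.
#' @export
kb_from_score <- function(delta_g, temperature = 300) {
  check_numeric_vector(delta_g, "delta_g")
  check_positive(temperature, "temperature")
  exp(-delta_g / (.R_KCAL * temperature))
}

#' Free energy from a binding constant
#'
#' Exact inverse of [kb_from_score()]: `dG = -R*T*ln(Kb)` in kcal/mol.
#'
#' @param k_b Binding constant(s), 1/M, > 0.
#' @param temperature Temperature (K). Default 300.
#' @return Free energy in kcal/mol.
#' @export
score_from_kb <- function(k_b, temperature = 300) {
  check_numeric_vector(k_b, "k_b", positive = TRUE)
  check_positive(temperature, "temperature")
  -.R_KCAL * temperature * log(k_b)
}

#' Classify the dominant binding forces
#'
#' Standard enthalpy/entropy sign heuristics for non-covalent protein-ligand
#' association: exothermic binding dominated by the enthalpic term points to
#' hydrogen bonding and van der Waals contacts; entropy-driven endothermic
#' binding to hydrophobic burial; negative enthalpy with a dominant positive
#' entropic term to electrostatics.
#'
#' @param delta_h Binding enthalpy (J/mol).
#' @param delta_s Binding entropy (J/(mol K)).
#' @param temperature Temperature (K) at which the terms are compared.
#' @return A single string labelling the dominant force.
#' @export
dominant_forces <- function(delta_h, delta_s, temperature = 298) {
  check_number(delta_h, "delta_h")
  check_number(delta_s, "delta_s")
  check_positive(temperature, "temperature")
  tds <- temperature * delta_s
  if (delta_h < 0 && delta_s < 0) {
    "hydrogen bond / van der Waals"
  } else if (delta_h > 0 && delta_s > 0) {
    "entropy-driven: hydrophobic"
  } else if (delta_h < 0 && delta_s >= 0) {
    if (abs(delta_h) > abs(tds)) {
      "enthalpy-driven: hydrogen bond / van der Waals"
    } else {
      "electrostatic"
    }
  } else {
    "indeterminate"
  }
}

#' Full thermodynamic report
#'
#' Runs [gibbs_free_energy()] at each fitted temperature and attaches the
#' [dominant_forces()] label (evaluated at the median temperature).
#'
#' @param fit A [vant_hoff_fit()].
#' @param temperatures Temperatures (K); defaults to the fit's own.
#' @return An object of class `thermo_report`: list with `table` (the
#'   [gibbs_free_energy()] data.frame), `delta_h`, `delta_s`, `force_label`.
#' @export
thermo_report <- function(fit, temperatures = fit$temperatures) {
  tab <- gibbs_free_energy(fit, temperatures)
  structure(
    list(
      table = tab,
      delta_h = fit$delta_h,
      delta_s = fit$delta_s,
      force_label = dominant_forces(fit$delta_h, fit$delta_s,
                                    stats::median(temperatures))
    ),
    class = "thermo_report"
  )
}

#' @export
print.thermo_report <- function(x, ...) {
  cat(sprintf("<thermo_report> dH = %.2f kJ/mol, dS = %.2f J/(mol K) [%s]\n",
              x$delta_h / 1000, x$delta_s, x$force_label))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  T = %.0f K: dG = %.2f kJ/mol, T*dS = %.2f kJ/mol\n",
                tab$temperature[i], tab$delta_g[i] / 1000,
                tab$t_delta_s[i] / 1000))
  }
  invisible(x)
}
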