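#' Free ligand concentration from total concentrations
#'
#' For `n` identical independent sites with site binding constant `Kb`, the
#' binding density is `Sigma_nu = n*Kb*Lf / (1 + Kb*Lf)` and mass conservation
#' reads `L_tot = Lf + Sigma_nu * P_tot`. Substituting gives the quadratic
#' `Kb*Lf^2 + (1 + Kb*(n*P_tot - L_tot))*Lf - L_tot = 0`, whose unique
#' non-negative root is returned using the numerically stable form of the
#' quadratic formula (no cancellation when the linear coefficient is large).
#'
#' @param ligand_total Total ligand concentration (mol/L, vectorised, >= 0).
#' @param protein_total Total protein concentration (mol/L, >= 0).
#' @param k_b Site binding constant (1/M, >= 0).
#' @param n_sites Number of identical independent sites (>= 0).
#' @return Free ligand concentration(s), `0 <= Lf <= ligand_total`.
#' @export
solve_free_ligand <- function(ligand_total, protein_total, k_b, n_sites) {
  check_numeric_vector(ligand_total, "ligand_total", non_negative = TRUE)
  check_non_negative(protein_total, "protein_total")
  check_non_negative(k_b, "k_b")
  check_non_negative(n_sites, "n_sites")
  if (k_b == 0 || protein_total == 0 || n_sites == 0) return(ligand_total)
  a <- k_b
  b <- 1 + k_b * (n_sites * protein_total - ligand_total)
  cc <- -ligand_total
  # stable root: q = -(b + sign(b)*sqrt(disc))/2; the non-negative root is
  # cc/q when b > 0 and q/a otherwise
  disc <- sqrt(b^2 - 4 * a * cc)
  q <- -0.5 * (b + sign(b + (b == 0)) * disc)
  lf <- ifelse(b > 0, cc / q, q / a)
  pmin(pmax(lf, 0), ligand_total)
}

#' Binding density of the identical-independent-site isotherm
#'
#' `Sigma_nu = n*Kb*Lf / (1 + Kb*Lf)`: the mean number of ligand molecules
#' bound per protein molecule, bounded by `n` at saturation.
#'
#' @param k_b Site binding constant (1/M, >= 0).
#' @param n_sites Number of sites (>= 0).
#' @param ligand_free Free ligand concentration(s) (mol/L, >= 0).
#' @return Binding density (unitless), in `[0, n_sites)`.
#' @export
binding_density <- function(k_b, n_sites, ligand_free) {
  check_non_negative(k_b, "k_b")
  check_non_negative(n_sites, "n_sites")
  check_numeric_vector(ligand_free, "ligand_free", non_negative = TRUE)
  n_sites * k_b * ligand_free / (1 + k_b * ligand_free)
}

#' Binding constant at a temperature from van't Hoff parameters
#'
#' Inverse of the van't Hoff regression:
#' `Ka(T) = exp(-dH/(R*T) + dS/R)` with `R = 8.314 J/(mol K)`.
#'
#' @param delta_h Enthalpy (J/mol).
#' @param delta_s Entropy (J/(mol K)).
#' @param temperature Temperature(s) (K), > 0.
#' @return Binding constant(s), 1/M.
#' @export
ka_at_temperature <- function(delta_h, delta_s, temperature) {
  check_number(delta_h, "delta_h")
  check_number(delta_s, "delta_s")
  check_numeric_vector(temperature, "temperature", positive = TRUE)
  exp(-delta_h / (.R_SI * temperature) + delta_s / .R_SI)
}

#' Simulation configuration
#'
#' Collects the ground-truth parameters of the static-quenching titration
#' forward model. Defaults mirror a typical serum-albumin experiment: protein
#' at 2, 4 and 8 uM, ligand added in 1 uM steps to 30 uM, three sites with
#' site constant 7e4 1/M.
#'
#' @param k_b_true Site binding constant (1/M), > 0.
#' @param n_sites_true Number of identical independent sites, >= 1.
#' @param q_max Maximum fractional quenching at saturation, in (0, 1].
#' @param f0 Intensity at zero ligand (arbitrary units), > 0.
#' @param protein_concs Protein concentrations (mol/L), one titration each.
#' @param ligand_grid Total ligand grid (mol/L), shared by all titrations.
#' @param noise_rel Multiplicative Gaussian noise sd (relative), >= 0.
#' @param seed Integer seed; each protein concentration gets its own RNG
#'   stream derived from `(seed, index)` so adding a series never perturbs
#'   the others.
#' @param temperature Temperature (K).
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(k_b_true = 7e4, n_sites_true = 3, q_max = 0.8,
                       f0 = 1000, protein_concs = c(2e-6, 4e-6, 8e-6),
                       ligand_grid = seq(0, 30e-6, by = 1e-6),
                       noise_rel = 0, seed = 1L, temperature = 288) {
  check_positive(k_b_true, "k_b_true")
  check_number(n_sites_true, "n_sites_true", lower = 1)
  check_number(q_max, "q_max", lower = 0, upper = 1, allow_zero_lower = TRUE)
  check_positive(f0, "f0")
  check_numeric_vector(protein_concs, "protein_concs", positive = TRUE)
  check_numeric_vector(ligand_grid, "ligand_grid", non_negative = TRUE)
  if (any(diff(ligand_grid) < 0)) {
    stop_validation("ligand_grid must be non-decreasing")
  }
  check_non_negative(noise_rel, "noise_rel")
  check_number(seed, "seed")
  check_positive(temperature, "temperature")
  structure(
    list(k_b_true = k_b_true, n_sites_true = n_sites_true, q_max = q_max,
         f0 = f0, protein_concs = protein_concs, ligand_grid = ligand_grid,
         noise_rel = noise_rel, seed = as.integer(seed),
         temperature = temperature),
    class = "sim_config"
  )
}

# Deterministic per-stream seed below 2^31, derived from (seed, index)
.stream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647)
}

#' Simulate static-quenching titrations with ground truth
#'
#' Forward model: at each (protein, ligand) pair the free ligand concentration
#' is solved exactly from mass balance ([solve_free_ligand()]), the binding
#' density `Sigma_nu` follows the identical-independent-site isotherm, and the
#' noiseless signal is `F = F0 * (1 - q_max * Sigma_nu / n)` — a linear signal
#' transduction in fractional site occupancy, the minimal monotone,
#' protein-concentration-independent choice. With one site and `q_max = 1`
#' this reduces exactly to the Stern-Volmer law in free ligand,
#' `F0/F = 1 + Kb*Lf`. Multiplicative Gaussian noise of relative sd
#' `noise_rel` is then applied with one independent RNG stream per protein
#' concentration.
#'
#' @param config A [sim_config()].
#' @return A list with `series` (list of [titration_series()], one per
#'   protein concentration) and `ground_truth` (class `ground_truth`: a
#'   data.frame of per-point records `protein_conc`, `ligand_total`,
#'   `ligand_free`, `sigma_nu`, `f_noiseless`, plus the config echo).
#' @export
simulate_titration <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  series <- vector("list", length(config$protein_concs))
  records <- vector("list", length(config$protein_concs))
  for (i in seq_along(config$protein_concs)) {
    p <- config$protein_concs[i]
    lf <- solve_free_ligand(config$ligand_grid, p, config$k_b_true,
                            config$n_sites_true)
    nu <- binding_density(config$k_b_true, config$n_sites_true, lf)
    f_clean <- config$f0 * (1 - config$q_max * nu / config$n_sites_true)
    f <- f_clean
    if (config$noise_rel > 0) {
      old_seed <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      set.seed(.stream_seed(config$seed, i))
      f <- f_clean * (1 + config$noise_rel *
                        stats::rnorm(length(f_clean)))
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      f <- pmax(f, .Machine$double.eps * config$f0)
    }
    series[[i]] <- titration_series(
      ligand_total = config$ligand_grid,
      intensity = f,
      protein_conc = p,
      temperature = config$temperature
    )
    records[[i]] <- data.frame(
      protein_conc = p,
      ligand_total = config$ligand_grid,
      ligand_free = lf,
      sigma_nu = nu,
      f_noiseless = f_clean
    )
  }
  gt <- structure(
    list(records = do.call(rbind, records), config = config),
    class = "ground_truth"
  )
  list(series = series, ground_truth = gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d records; true Kb = %.4g 1/M, n = %g, q_max = %g, noise = %g, seed = %d\n",
    nrow(x$records), x$config$k_b_true, x$config$n_sites_true,
    x$config$q_max, x$config$noise_rel, x$config$seed))
  invisible(x)
}

#' Construct a TCSPC decay trace
#'
#' @param time Strictly increasing time grid (ns).
#' @param counts Non-negative counts per bin.
#' @return An object of class `decay_trace` with fields `time`, `counts`,
#'   `total_counts`.
#' @export
decay_trace <- function(time, counts) {
  check_numeric_vector(time, "time")
  check_numeric_vector(counts, "counts", non_negative = TRUE)
  if (!is_strictly_increasing(time)) {
    stop_validation("time must be strictly increasing")
  }
  if (length(time) != length(counts)) {
    stop_validation("time and counts must have equal length")
  }
  structure(list(time = time, counts = counts,
                 total_counts = sum(counts)),
            class = "decay_trace")
}

#' Simulate a multiexponential TCSPC decay
#'
#' Expected counts per bin follow `I(t) = sum_i alpha_i * exp(-t / tau_i)`,
#' scaled so the peak bin holds `peak_counts`; each bin is then Poisson
#' sampled (or returned as its expectation when `poisson_noise = FALSE`).
#'
#' @param amplitudes Relative component amplitudes (>= 0, not all zero).
#' @param lifetimes Component lifetimes (ns, > 0), same length.
#' @param time_range Trace duration (ns). Default 25.
#' @param n_bins Number of bins. Default 256.
#' @param peak_counts Expected counts in the peak bin. Default 1e4.
#' @param seed Integer seed for the Poisson sampling.
#' @param poisson_noise Logical; `FALSE` returns noiseless expected counts.
#' @return A [decay_trace()].
#' @export
simulate_decay <- function(amplitudes, lifetimes, time_range = 25,
                           n_bins = 256, peak_counts = 1e4, seed = 1L,
                           poisson_noise = TRUE) {
  check_numeric_vector(amplitudes, "amplitudes", non_negative = TRUE)
  check_numeric_vector(lifetimes, "lifetimes", positive = TRUE)
  if (length(amplitudes) != length(lifetimes)) {
    stop_validation("amplitudes and lifetimes must have equal length")
  }
  if (sum(amplitudes) <= 0) stop_validation("amplitudes must not all be zero")
  check_positive(time_range, "time_range")
  check_number(n_bins, "n_bins", lower = 2)
  check_positive(peak_counts, "peak_counts")
  t <- seq(0, time_range, length.out = n_bins)
  expected <- colSums(amplitudes * exp(outer(-1 / lifetimes, t)))
  expected <- expected / max(expected) * peak_counts
  counts <- expected
  if (poisson_noise) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(as.integer(seed))
    counts <- stats::rpois(length(expected), expected)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  decay_trace(time = t, counts = counts)
}
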