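#' Stern-Volmer fit
#'
#' Fits the Stern-Volmer relation `F0/F = 1 + K_SV * [Q]` by ordinary least
#' squares of `F0/F` against total quencher concentration. `F0` is the
#' intensity at the zero-ligand point, which must be present. The intercept is
#' fitted, not pinned to 1; its deviation from 1 is a useful diagnostic of
#' curvature or inner-filter residuals.
#'
#' @param series A [titration_series()] with at least 3 points including
#'   `ligand_total = 0`.
#' @return An object of class `stern_volmer_fit`: list with `k_sv` (1/M),
#'   `intercept`, `k_sv_stderr`, `intercept_stderr`, `r_squared`,
#'   `temperature` (K) and `n_points`.
#' @export
stern_volmer_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  q <- series$ligand_total
  if (length(q) < 3L) stop_validation("at least 3 titration points required")
  if (q[1] != 0) stop_validation("no zero-ligand point: F0 undefined")
  f0 <- series$intensity[1]
  y <- f0 / series$intensity
  fit <- stats::lm(y ~ q)
  sm <- suppressWarnings(summary(fit))
  structure(
    list(
      k_sv = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      k_sv_stderr = unname(sm$coefficients[2, 2]),
      intercept_stderr = unname(sm$coefficients[1, 2]),
      r_squared = sm$r.squared,
      temperature = series$temperature,
      n_points = length(q)
    ),
    class = "stern_volmer_fit"
  )
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf(
    "<stern_volmer_fit> K_SV = %.4g +/- %.2g 1/M, intercept = %.4f, r2 = %.4f (T = %.0f K)\n",
    x$k_sv, x$k_sv_stderr, x$intercept, x$r_squared, x$temperature))
  invisible(x)
}

#' Double-logarithmic binding fit
#'
#' Fits the double-log binding-equilibrium linearisation
#' `log10((F0-F)/F) = n*log10(Ka) + n*log10([L]tot - ((F0-F)/Fd)*[P]tot)`
#' by OLS: the slope is the number of binding sites `n` and the intercept is
#' `n*log10(Ka)`. The bracket subtracts the ligand bound to protein, estimated
#' from the fractional signal change; `Fd` (the denominator of that fraction)
#' is `F` by default, with `bracket_denominator = "F0"` selecting the common
#' variant.
#'
#' Points with `F0 - F <= 0` (no quenching, typically noise at low ligand) or
#' with a non-positive bracket term are dropped with a warning; at least 3
#' usable points must remain.
#'
#' @param series A [titration_series()] with a zero-ligand point.
#' @param bracket_denominator `"F"` (default) or `"F0"`.
#' @return An object of class `double_log_fit`: list with `k_a` (1/M),
#'   `n_sites`, `k_a_stderr`, `n_sites_stderr`, `r_squared`, `temperature`,
#'   `points_used`, `points_dropped`.
#' @export
double_log_fit <- function(series, bracket_denominator = c("F", "F0")) {
  stopifnot(inherits(series, "titration_series"))
  bracket_denominator <- match.arg(bracket_denominator)
  q <- series$ligand_total
  if (length(q) < 3L) stop_validation("at least 3 titration points required")
  if (q[1] != 0) stop_validation("no zero-ligand point: F0 undefined")
  f0 <- series$intensity[1]
  f <- series$intensity[-1]
  lt <- q[-1]
  dfrac <- (f0 - f)
  fd <- if (bracket_denominator == "F") f else rep(f0, length(f))
  bracket <- lt - (dfrac / fd) * series$protein_conc
  ok <- dfrac > 0 & bracket > 0
  dropped <- sum(!ok)
  if (dropped > 0) {
    warning(sprintf(
      "double_log_fit: dropped %d point(s) with F0-F <= 0 or non-positive bracket",
      dropped))
  }
  if (sum(ok) < 3L) {
    stop_validation("fewer than 3 usable points after filtering")
  }
  x <- log10(bracket[ok])
  y <- log10(dfrac[ok] / f[ok])
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  n_sites <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (n_sites <= 0) stop_validation("non-positive fitted slope: no binding signal")
  n_se <- unname(sm$coefficients[2, 2])
  i_se <- unname(sm$coefficients[1, 2])
  log10_ka <- intercept / n_sites
  k_a <- 10^log10_ka
  # delta-method propagation for Ka = 10^(intercept/slope), independent errors
  dka_di <- k_a * log(10) / n_sites
  dka_dn <- -k_a * log(10) * intercept / n_sites^2
  k_a_stderr <- sqrt((dka_di * i_se)^2 + (dka_dn * n_se)^2)
  structure(
    list(
      k_a = k_a,
      n_sites = n_sites,
      k_a_stderr = k_a_stderr,
      n_sites_stderr = n_se,
      r_squared = sm$r.squared,
      temperature = series$temperature,
      points_used = sum(ok),
      points_dropped = dropped,
      bracket_denominator = bracket_denominator
    ),
    class = "double_log_fit"
  )
}

#' @export
print.double_log_fit <- function(x, ...) {
  cat(sprintf(
    "<double_log_fit> K_a = %.4g 1/M, n = %.3f +/- %.3f, r2 = %.4f (%d points, T = %.0f K)\n",
    x$k_a, x$n_sites, x$n_sites_stderr, x$r_squared, x$points_used,
    x$temperature))
  invisible(x)
}

#' Classify the quenching mechanism
#'
#' Static (ground-state complex) quenching is diagnosed when the Stern-Volmer
#' constant decreases with temperature and, when time-resolved data are
#' available, the excited-state lifetime is essentially unchanged by the
#' quencher (`tau0/tau` near 1). Dynamic (collisional) quenching shows the
#' opposite temperature trend, with `tau0/tau` tracking `F0/F`. Conflicting or
#' insufficient evidence yields `"indeterminate"`.
#'
#' @param fits List of [stern_volmer_fit()] objects at two or more
#'   temperatures (any order; sorted internally).
#' @param lifetime_ratios Optional numeric vector of `tau0/tau` ratios across
#'   the titration (may be empty).
#' @param ratio_threshold Maximum mean `|tau0/tau - 1|` compatible with an
#'   unchanged lifetime. Default 0.05.
#' @return An object of class `quenching_verdict`: list with `mechanism`
#'   (`"static"`, `"dynamic"` or `"indeterminate"`), `ksv_trend` (-1, 0 or
#'   +1), and `mean_lifetime_ratio_deviation` (NA when no ratios given).
#' @export
classify_quenching <- function(fits, lifetime_ratios = numeric(),
                               ratio_threshold = 0.05) {
  stopifnot(is.list(fits),
            all(vapply(fits, inherits, logical(1), "stern_volmer_fit")))
  check_number(ratio_threshold, "ratio_threshold", lower = 0)
  temps <- vapply(fits, `[[`, numeric(1), "temperature")
  ksv <- vapply(fits, `[[`, numeric(1), "k_sv")[order(temps)]
  have_ratios <- length(lifetime_ratios) > 0
  dev <- if (have_ratios) mean(abs(lifetime_ratios - 1)) else NA_real_

  trend <- if (length(ksv) < 2L) 0L
  else if (all(diff(ksv) < 0)) -1L
  else if (all(diff(ksv) > 0)) 1L
  else 0L

  mechanism <-
    if (trend == -1L && (!have_ratios || dev < ratio_threshold)) "static"
    else if (trend == 1L && (!have_ratios || dev >= ratio_threshold)) "dynamic"
    else "indeterminate"

  structure(
    list(mechanism = mechanism, ksv_trend = trend,
         mean_lifetime_ratio_deviation = dev,
         ratio_threshold = ratio_threshold),
    class = "quenching_verdict"
  )
}

#' @export
print.quenching_verdict <- function(x, ...) {
  cat(sprintf(
    "<quenching_verdict> mechanism = %s (K_SV trend %+d, mean |tau0/tau - 1| = %s)\n",
    x$mechanism, x$ksv_trend,
    if (is.na(x$mean_lifetime_ratio_deviation)) "n/a"
    else sprintf("%.3f", x$mean_lifetime_ratio_deviation)))
  invisible(x)
}
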