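#' Build a quench curve for the IDF analysis
#'
#' Converts one titration into a monotone map from quench percentage `dF` to
#' total ligand concentration. The interpolant is shape-preserving monotone
#' piecewise cubic (Fritsch-Carlson), imposed on the `(dF, L_tot)` knots; no
#' parametric sigmoid is assumed, keeping the analysis model-independent.
#'
#' With `denoise = TRUE` (default) the intensity series is first passed
#' through a cross-validated smoothing spline in `L_tot`, and both the
#' zero-ligand reference `F0` and the quench percentages are taken from the
#' smoothed curve, so the reference and the curve share boundary errors that
#' largely cancel in the ratio. Denoising only engages when the smoothing
#' residuals exceed one part in 10^4 of the peak intensity; clean (noiseless
#' or replicate-averaged) data pass through exactly, and the interpolant then
#' reproduces every knot.
#'
#' Small residual non-monotonicities are pooled by isotonic regression; a
#' drop in `dF` exceeding `noise_tolerance` percentage points is treated as
#' a data error. Knots left tied after pooling have their `L_tot` values
#' averaged so the inverse map is single-valued.
#'
#' @param series A [titration_series()] with >= 5 points and a zero-ligand
#'   point.
#' @param noise_tolerance Maximum tolerated decrease in `dF` between
#'   consecutive points (percentage points). Default 2.
#' @param denoise Smooth the intensity series before constructing the
#'   quench map (see Details). Default `TRUE`.
#' @return An object of class `quench_curve`: list with `protein_conc`,
#'   `knots` (data.frame `ligand_total`, `delta_f`), `range` (of `dF`),
#'   `denoised` (logical, whether smoothing engaged), and the interpolating
#'   function accessible through [predict.quench_curve()].
#' @export
build_quench_curve <- function(series, noise_tolerance = 2, denoise = TRUE) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$ligand_total) < 5L) {
    stop_validation("at least 5 titration points required")
  }
  if (series$ligand_total[1] != 0) {
    stop_validation("no zero-ligand point: F0 undefined")
  }
  check_non_negative(noise_tolerance, "noise_tolerance")
  intensity <- series$intensity
  denoised <- FALSE
  if (isTRUE(denoise) && length(intensity) >= 8L) {
    fit <- stats::smooth.spline(series$ligand_total, intensity)
    smoothed <- stats::predict(fit, series$ligand_total)$y
    # engage only when the data actually carry high-frequency noise;
    # smooth (noiseless or pre-averaged) input passes through untouched
    if (stats::sd(intensity - smoothed) / max(intensity) > 1e-4) {
      intensity <- smoothed
      denoised <- TRUE
    }
  }
  f0 <- intensity[1]
  df <- quench_percent(f0, intensity)
  drops <- -diff(df)
  if (any(drops > noise_tolerance)) {
    stop_validation(sprintf(
      "quench percentage decreases by %.2f points (tolerance %.2f): curve is not monotone",
      max(drops), noise_tolerance))
  }
  # pool adjacent violators, then average ties so knots strictly increase
  df_iso <- stats::isoreg(seq_along(df), df)$yf
  agg <- stats::aggregate(
    list(ligand_total = series$ligand_total),
    by = list(delta_f = df_iso), FUN = mean)
  agg <- agg[order(agg$delta_f), ]
  if (nrow(agg) < 2L) {
    stop_validation("curve degenerate: fewer than 2 distinct quench levels")
  }
  interp <- stats::splinefun(agg$delta_f, agg$ligand_total,
                             method = "monoH.FC")
  structure(
    list(
      protein_conc = series$protein_conc,
      knots = data.frame(ligand_total = agg$ligand_total,
                         delta_f = agg$delta_f),
      range = range(agg$delta_f),
      denoised = denoised,
      interpolant = interp
    ),
    class = "quench_curve"
  )
}


#' Invert a quench curve
#'
#' Reads the total ligand concentration off the curve at given quench levels.
#'
#' @param object A [build_quench_curve()] result.
#' @param delta_f Quench level(s) (percent), inside the curve's range.
#' @param ... Unused.
#' @return Total ligand concentration(s) (mol/L).
#' @export
predict.quench_curve <- function(object, delta_f, ...) {
  check_numeric_vector(delta_f, "delta_f")
  if (any(delta_f < object$range[1]) || any(delta_f > object$range[2])) {
    stop_validation(sprintf(
      "delta_f outside curve range [%.3f, %.3f]",
      object$range[1], object$range[2]))
  }
  object$interpolant(delta_f)
}

#' @export
print.quench_curve <- function(x, ...) {
  cat(sprintf(
    "<quench_curve> [P] = %.3g M, %d knots, dF range [%.2f, %.2f]%%\n",
    x$protein_conc, nrow(x$knots), x$range[1], x$range[2]))
  invisible(x)
}

#' Extract binding density and free ligand by the IDF construction
#'
#' The interaction-density-function step: at a common quench level `dF`, the
#' binding density `Sigma_nu` and free ligand concentration are the same for
#' every protein concentration (the signal change per protein reflects the
#' same fractional occupancy). Mass conservation
#' `L_tot = L_free + Sigma_nu * P_tot` then makes `L_tot` read off each curve
#' an affine function of `P_tot`: OLS of `L_tot` against `P_tot` per level
#' gives `Sigma_nu` as the slope and `L_free` as the intercept.
#'
#' @param curves List of >= 2 [build_quench_curve()] objects at distinct
#'   protein concentrations.
#' @param levels Quench levels (percent) at which to section the curves, or
#'   `NULL` (default) for `n_levels` levels evenly spaced over the
#'   intersection of all curves' ranges, trimmed by `trim` at each end.
#' @param n_levels Number of automatic levels. Default 10.
#' @param trim Fraction of the common range trimmed at each end for automatic
#'   levels. Default 0.05.
#' @param drop_negative_free Exclude levels whose fitted intercept (free
#'   ligand) is negative — unphysical, typically extrapolation noise.
#'   Default `TRUE`; excluded levels are kept in the output with
#'   `excluded = TRUE` and a warning.
#' @return A data.frame of class `idf_points`: per level `delta_f_level`,
#'   `sigma_nu`, `ligand_free` (mol/L), `slope_stderr`, `intercept_stderr`,
#'   `n_curves_used`, `excluded`.
#' @export
idf_extract <- function(curves, levels = NULL, n_levels = 10, trim = 0.05,
                        drop_negative_free = TRUE) {
  stopifnot(is.list(curves),
            all(vapply(curves, inherits, logical(1), "quench_curve")))
  if (length(curves) < 2L) {
    stop_validation("at least 2 quench curves required")
  }
  p <- vapply(curves, `[[`, numeric(1), "protein_conc")
  if (length(unique(p)) < length(p)) {
    stop_validation("protein concentrations must be distinct")
  }
  lo <- max(vapply(curves, function(cv) cv$range[1], numeric(1)))
  hi <- min(vapply(curves, function(cv) cv$range[2], numeric(1)))
  if (lo >= hi) {
    stop_validation("curves share no common quench-percentage range")
  }
  if (is.null(levels)) {
    check_number(n_levels, "n_levels", lower = 1)
    check_number(trim, "trim", lower = 0, upper = 0.49)
    span <- hi - lo
    levels <- seq(lo + trim * span, hi - trim * span, length.out = n_levels)
  } else {
    check_numeric_vector(levels, "levels")
    if (any(levels < lo) || any(levels > hi)) {
      stop_validation("requested levels fall outside the common curve range")
    }
  }
  rows <- lapply(levels, function(lv) {
    ltot <- vapply(curves, function(cv) predict(cv, lv), numeric(1))
    fit <- stats::lm(ltot ~ p)
    sm <- suppressWarnings(summary(fit))
    se <- if (length(p) > 2L) sm$coefficients[, 2] else c(NA_real_, NA_real_)
    data.frame(
      delta_f_level = lv,
      sigma_nu = unname(stats::coef(fit)[2]),
      ligand_free = unname(stats::coef(fit)[1]),
      slope_stderr = unname(se[2]),
      intercept_stderr = unname(se[1]),
      n_curves_used = length(p)
    )
  })
  out <- do.call(rbind, rows)
  out$excluded <- FALSE
  if (drop_negative_free && any(out$ligand_free < 0)) {
    bad <- out$ligand_free < 0
    warning(sprintf(
      "idf_extract: %d level(s) with negative fitted free ligand excluded",
      sum(bad)))
    out$excluded[bad] <- TRUE
  }
  if (any(out$sigma_nu < 0)) {
    bad <- out$sigma_nu < 0 & !out$excluded
    if (any(bad)) {
      warning(sprintf(
        "idf_extract: %d level(s) with negative binding density excluded",
        sum(bad)))
      out$excluded[bad] <- TRUE
    }
  }
  class(out) <- c("idf_points", "data.frame")
  out
}

#' Scatchard regression on IDF points
#'
#' For `n` identical independent sites the Scatchard plot
#' `Sigma_nu / L_free` versus `Sigma_nu` is linear:
#' `Sigma_nu/L_free = n*Kb - Kb*Sigma_nu`. OLS gives `Kb = -slope` and
#' `n = intercept / Kb`. Linearity (high r-squared) is the signature of
#' non-cooperative equivalent sites; curvature flags cooperativity or site
#' heterogeneity.
#'
#' @param points An [idf_extract()] result (excluded levels are skipped), or
#'   any data.frame with `sigma_nu` and `ligand_free` columns.
#' @param r2_linear_threshold Minimum r-squared to call the plot linear
#'   (non-cooperative). Default 0.95.
#' @return An object of class `scatchard_fit`: list with `k_b` (1/M),
#'   `n_sites`, `k_b_stderr`, `n_sites_stderr`, `r_squared`,
#'   `cooperativity_flag` (`"non_cooperative_linear"` or `"nonlinear"`),
#'   `n_points`.
#' @export
scatchard_fit <- function(points, r2_linear_threshold = 0.95) {
  stopifnot(is.data.frame(points),
            all(c("sigma_nu", "ligand_free") %in% names(points)))
  if ("excluded" %in% names(points)) points <- points[!points$excluded, ]
  points <- points[points$ligand_free > 0, ]
  if (nrow(points) < 3L) {
    stop_validation("at least 3 usable points (ligand_free > 0) required")
  }
  x <- points$sigma_nu
  y <- points$sigma_nu / points$ligand_free
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (is.na(slope) || slope >= 0) {
    stop_validation(
      "no saturable binding detected (non-negative or undefined Scatchard slope)")
  }
  k_b <- -slope
  n_sites <- intercept / k_b
  slope_se <- unname(sm$coefficients[2, 2])
  int_se <- unname(sm$coefficients[1, 2])
  # n = -intercept/slope: delta method with independent errors
  n_se <- abs(n_sites) * sqrt((int_se / intercept)^2 + (slope_se / slope)^2)
  structure(
    list(
      k_b = k_b,
      n_sites = n_sites,
      k_b_stderr = slope_se,
      n_sites_stderr = n_se,
      r_squared = sm$r.squared,
      cooperativity_flag = if (sm$r.squared >= r2_linear_threshold) {
        "non_cooperative_linear"
      } else {
        "nonlinear"
      },
      n_points = nrow(points)
    ),
    class = "scatchard_fit"
  )
}

#' @export
print.scatchard_fit <- function(x, ...) {
  cat(sprintf(
    "<scatchard_fit> K_b = %.4g 1/M, n = %.3f, r2 = %.4f [%s] (%d points)\n",
    x$k_b, x$n_sites, x$r_squared, x$cooperativity_flag, x$n_points))
  invisible(x)
}

#' Full IDF / Scatchard analysis from titration series
#'
#' Convenience wrapper: build quench curves from >= 2 titrations at distinct
#' protein concentrations, extract (binding density, free ligand) pairs at
#' common quench levels, and fit the Scatchard line.
#'
#' @param series_list List of [titration_series()] at distinct protein
#'   concentrations (same temperature).
#' @param ... Passed to [idf_extract()] (`levels`, `n_levels`, `trim`, ...).
#' @param noise_tolerance,denoise Passed to [build_quench_curve()].
#' @param r2_linear_threshold Passed to [scatchard_fit()].
#' @return A list with `curves`, `points` and `fit`.
#' @export
idf_analysis <- function(series_list, ..., noise_tolerance = 2,
                         denoise = TRUE, r2_linear_threshold = 0.95) {
  curves <- lapply(series_list, build_quench_curve,
                   noise_tolerance = noise_tolerance, denoise = denoise)
  points <- idf_extract(curves, ...)
  fit <- scatchard_fit(points, r2_linear_threshold = r2_linear_threshold)
  list(curves = curves, points = points, fit = fit)
}
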