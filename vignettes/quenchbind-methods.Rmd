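---
title: "Methods: binding analysis from fluorescence quenching titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding analysis from fluorescence quenching titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

# The measurement and the models

A ligand that binds near a protein's intrinsic fluorophore (for serum
albumins, a single tryptophan) reduces the emission intensity as it is
titrated in. `quenchbind` turns such titrations into binding parameters
through several complementary routes, each with different assumptions, and
adds the surrounding analyses a full characterisation needs: quenching
mechanism classification, van't Hoff thermodynamics, excited-state lifetime
analysis, ellipticity conversion and docking-score conversion.

All concentrations are handled internally in mol/L, temperatures in K, path
lengths in cm and lifetimes in ns; file dialects convert at the boundary
(`read_titration_table()`), which removes the usual silent factor-of-10^6
errors between micromolar data files and molar equations.

## Steady-state quenching: Stern-Volmer and the double-log fit

With `F0` the intensity at zero ligand and `F` at quencher concentration
`[Q]`, the Stern-Volmer law `F0/F = 1 + K_SV [Q]` is fitted by OLS
(`stern_volmer_fit()`). The intercept is estimated rather than pinned at 1;
its deviation from 1 is a diagnostic for curvature or residual inner-filter
effects. Intensities can be inner-filter corrected at load time by
`F_corr = F_obs 10^((A_ex + A_em)/2)` when excitation/emission absorbances
are available; a flag on the series records which path was taken. When the
quenching acts by ground-state complex formation, `K_SV` is an association
constant.

The double-log linearisation
`log10((F0-F)/F) = n log10(Ka) + n log10([L]_tot - ((F0-F)/Fd)[P]_tot)`
(`double_log_fit()`) estimates an association constant and an apparent site
number from a single titration. The bracket subtracts bound ligand
estimated from the fractional signal change. Two conventions circulate for
the denominator `Fd` of that fraction; the default here is `Fd = F`, with
`bracket_denominator = "F0"` selecting the more common variant. The choice
matters little in the weak-depletion limit, where both reduce to
`log10` of free ligand. Points with `F0 - F <= 0` (noise or enhancement at
low quencher) are dropped with a warning rather than failing the fit.

## Quenching mechanism

Static (complex-forming) and dynamic (collisional) quenching are
distinguished by two orthogonal observables: the temperature trend of
`K_SV` (binding weakens with temperature, collisions accelerate) and the
excited-state lifetime (untouched by static quenching, shortened
proportionally by dynamic quenching). `classify_quenching()` encodes the
standard decision table: a strictly decreasing `K_SV(T)` with mean
`|tau0/tau - 1|` below a threshold (default 0.05, since "essentially
unchanged" needs an operational definition) is static; the reverse pattern
is dynamic; anything conflicting is reported as indeterminate rather than
guessed.

## The interaction density function (IDF) and Scatchard analysis

The double-log fit assumes a binding model. The IDF construction does not:
if the fractional quenching `dF = |F - F0|/F0 * 100` is a single monotone
function of the binding density `Sigma_nu` (ligands bound per protein),
then at a common `dF` level every titration — whatever its total protein
concentration `[P]` — has the same `Sigma_nu` and the same free ligand
concentration `[L]_free`. Mass conservation
`[L]_tot = [L]_free + Sigma_nu [P]` then makes the total ligand
concentrations read off several curves at one level an affine function of
`[P]`: the slope is `Sigma_nu`, the intercept `[L]_free`
(`idf_extract()`). A Scatchard regression
`Sigma_nu/[L]_free = n Kb - Kb Sigma_nu` over the extracted pairs gives the
site number and the site binding constant (`scatchard_fit()`); linearity of
that plot (r-squared at or above 0.95 by default) is the operational
signature of equivalent independent sites.

Design choices in this chain that were genuinely open:

* **Curve representation.** Each titration becomes a monotone
  shape-preserving piecewise-cubic (Fritsch-Carlson) interpolant of
  `[L]_tot` as a function of `dF` — no parametric sigmoid is imposed, since
  model independence is the point of the method. Duplicate `dF` knots are
  averaged; non-monotonicity beyond `noise_tolerance` (default 2 percentage
  points) is treated as a data error rather than silently repaired.
* **Denoising.** With `denoise = TRUE` (default) the intensity series is
  first smoothed with a cross-validated smoothing spline, and the
  zero-ligand reference is taken from the same smooth, so reference and
  curve share boundary errors that partially cancel in the quench ratio.
  A residual-based detector (residual sd above one part in 10^4 of the peak
  intensity) keeps clean data untouched, so on noiseless input the
  interpolant still passes through every measured point exactly. The
  rationale is quantitative: reading a level off an interpolant that passes
  through noisy knots transmits the full point noise into the level
  regression, and the per-curve error of the zero-ligand reference shifts
  whole curves coherently; both effects are reduced substantially by the
  shared smooth (see Limitations).
* **Level grid.** 10 levels evenly spaced over the intersection of the
  curves' `dF` ranges, trimmed 5% at each end, all configurable. The
  extremes of the common range are the least informative: the low end
  divides by tiny free-ligand concentrations, the high end reads the
  flattest part of the highest-concentration curve.
* **Unphysical levels.** Levels whose fitted `[L]_free` is negative are
  excluded (with a warning) rather than clamped at zero, which would bias
  the Scatchard line.
* **Regressions.** Unweighted OLS throughout, matching the linear-plot
  treatment conventional for these analyses.

## Van't Hoff thermodynamics and force classification

`vant_hoff_fit()` regresses `ln Ka` on `1/T` (R = 8.314 J/(mol K)), giving
`dH = -R x slope` and `dS = R x intercept` under the usual assumption of
temperature-independent enthalpy over the measured range (no heat-capacity
term — a deliberate non-goal). `gibbs_free_energy()` evaluates
`dG = dH - T dS` with uncertainty propagated treating the two estimates as
independent. `dominant_forces()` applies the standard sign/magnitude
heuristics (enthalpy-dominated exothermic binding: hydrogen bonds / van der
Waals; both terms positive: hydrophobic; negative enthalpy with dominant
entropic term: electrostatic).

`kb_from_score()` converts docking energies (kcal/mol) with
R = 1.987e-3 kcal/(mol K) at a default 300 K — the thermostat temperature
conventional for the simulations such scores come from, and the value at
which the conversion reproduces typical published constants at two
significant figures.

## Lifetimes

`fit_multiexponential()` fits `I(t) = baseline + sum_i A_i exp(-t/tau_i)`
to TCSPC histograms from the peak bin onward (tail fit; no
instrument-response deconvolution, appropriate when lifetimes are well
above the instrument response). The solver is variable projection: for
fixed lifetimes the amplitudes and baseline are linear and solved by
weighted non-negative least squares, so amplitudes are non-negative by
construction; the outer optimisation is over log-lifetimes from a
deterministic grid of 5 starts log-spaced between the bin width and half
the time range (no RNG in fitting). Weights begin at the Neyman estimate
`1/max(counts, 1)` and are re-derived once from the fitted model: pure
observed-count weighting overweights downward fluctuations and biases
lifetimes low by several percent at 10^4 peak counts, which the single
reweighting pass removes (verified in the tests by parameter recovery).
The intensity-weighted average lifetime `sum(a t^2)/sum(a t)`
(`average_lifetime()`) generalises the two-component formula to 1-3
components and feeds the `tau0/tau` quenching diagnostic.

## Ellipticity

`mean_residue_ellipticity()` is the standard per-residue normalisation
`theta / (10 [P] l n)`. The residue count is used for `n` (not peptide
bonds). Secondary-structure deconvolution is out of scope.

# The synthetic-data generator

Because raw spectra for this class of experiment are rarely deposited,
every analysis stage is validated against a forward model with exact ground
truth (`simulate_titration()`):

* `n` identical independent sites with site constant `Kb`; free ligand from
  exact mass balance (the stable quadratic root, `solve_free_ligand()`,
  cross-checked in the tests against an independent bisection solver to
  1e-10);
* linear signal transduction `F = F0 (1 - q_max Sigma_nu / n)` — the
  minimal monotone, protein-independent choice, which reduces exactly to
  the Stern-Volmer law in free ligand when `n = 1, q_max = 1`;
* multiplicative Gaussian intensity noise with one RNG stream per protein
  concentration, derived deterministically from `(seed, index)`, so adding
  a titration never perturbs existing ones.

Defaults mirror a typical serum-albumin design: protein at 2, 4 and 8 uM,
ligand 0-30 uM in 1 uM steps, 288 K, `Kb = 7e4` 1/M, `n = 3`,
`q_max = 0.8` (partial quenching at saturation is typical of real
protein-ligand pairs; complete quenching is the limiting assumption of the
closed-form models and can be selected with `q_max = 1`). `ground_truth`
records `(L_free, Sigma_nu, F)` per point with mass balance exact to
machine precision.

What the generator does **not** emulate: spectral shapes and wavelength
structure, collisional quenching kinetics, inner-filter effects (the
correction is tested separately on constructed absorbances), dilution, and
instrument drift. Passing recovery tests therefore demonstrates estimator
correctness under the stated noise model, not robustness to every artefact
of real spectra.

`simulate_decay()` produces Poisson-sampled multiexponential histograms
(default 25 ns over 256 bins, 10^4 peak counts) for the lifetime module.

# Numerical choices and degenerate inputs

* Free-ligand quadratic solved in the cancellation-free form; clamped to
  `[0, L_tot]` against rounding at the boundaries.
* Interpolation inversion refuses queries outside a curve's observed `dF`
  range rather than extrapolating.
* Scatchard fits with non-negative or undefined slope raise "no saturable
  binding detected"; constant-`Sigma_nu` inputs are caught the same way.
* Two-point van't Hoff fits return exact parameters with `NA` standard
  errors (no residual degrees of freedom) rather than fabricated ones.
* The decay fitter requires 10 bins per component past the peak and
  reports reduced chi-squared so over-parameterised fits are visible.

# Problem sizes used in the shipped tests

The test suite and the results-reproduction script run entirely on
generated data: titrations of 13-31 points across 3 protein concentrations,
100-replicate noise studies for the IDF chain, 50-replicate Poisson decay
studies at 256-1024 bins, and a 1000-case randomized mass-balance oracle
comparison. These sizes were chosen to estimate medians stably while
keeping a full run in the low minutes on one core.

# Known limitations

* **The IDF chain is noise-hungry with few protein concentrations.** With
  three curves, the per-level mass-balance regression has a single residual
  degree of freedom, and the per-curve normalisation error (the zero-ligand
  reference is itself a noisy measurement; no extrapolation or smoothing
  estimator we tested pins it below ~0.8% relative at 1% point noise)
  shifts whole curves coherently. At 1% multiplicative intensity noise the
  recovered `Kb` therefore scatters widely across replicates even with
  denoising (roughly a factor of two interquartile range), with median
  errors near 10% — while a parametric joint fit of the same data recovers
  `Kb` to a few percent. The model-independence of the IDF construction is
  bought with a real statistical cost; with noisy data, use more protein
  concentrations, replicate titrations, or treat the IDF result as a
  consistency check on a model-based fit.
* No heat-capacity term in the van't Hoff analysis; no cooperative or
  multi-class Scatchard decomposition; no IRF deconvolution or global
  lifetime analysis; no spectral baseline handling — all deliberate
  non-goals.
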