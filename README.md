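# quenchbind

Quantitative characterisation of small-molecule binding to proteins from
fluorescence quenching titrations, for spectroscopists and binding-assay
analysts who have intensity-versus-ligand tables (plus, optionally, TCSPC
decay histograms and CD ellipticities) and want binding constants, site
counts, thermodynamics and a quenching-mechanism verdict out the other end.

## What it computes

For a titration of ligand `[Q]` into protein with intrinsic fluorescence
`F` (unquenched `F0`):

- **Stern–Volmer fit** — OLS of `F0/F = 1 + K_SV·[Q]`; the temperature
  trend of `K_SV`, together with lifetime ratios `τ0/τ`, classifies the
  quenching as static (ground-state complex) or dynamic (collisional).
- **Double-log binding fit** —
  `log₁₀((F0−F)/F) = n·log₁₀(K_a) + n·log₁₀([Q]_tot − ((F0−F)/F)·[P]_tot)`,
  giving an association constant `K_a` and apparent site number `n` from a
  single titration.
- **Interaction density function (IDF) + Scatchard** — model-independent:
  equal fractional quenching ΔF across titrations at several protein
  concentrations implies equal binding density Σν and free ligand
  `[Q]_free`; mass conservation `[Q]_tot = [Q]_free + Σν·[P]_tot` turns
  curve sections into (Σν, `[Q]_free`) pairs, and the Scatchard line
  `Σν/[Q]_free = n·K_b − K_b·Σν` yields the site count and site constant.
- **Van't Hoff analysis** — `ln K_a` vs `1/T` gives ΔH and ΔS;
  `ΔG = ΔH − T·ΔS`; sign/magnitude heuristics label the dominant binding
  forces.
- **TCSPC lifetimes** — multiexponential tail fits
  `I(t) = Σ αᵢ·e^(−t/τᵢ)` with Poisson weighting and the
  intensity-weighted average `τ_avg = Σαᵢτᵢ²/Σαᵢτᵢ`.
- **Supporting conversions** — inner-filter correction
  `F_corr = F_obs·10^((A_ex+A_em)/2)`, Beer–Lambert concentrations, mean
  residue ellipticity `θ/(10·[P]·l·n)`, and docking-score conversion
  `K_b = e^(−ΔG/RT)`.
- **Forward simulator with ground truth** — n-site independent-site
  titrations with exact mass balance and Poisson-noised decays, so every
  estimator in the package is validated by parameter recovery.

See `vignettes/quenchbind-methods.Rmd` for the models, assumptions and
design decisions.

## Worked example

Thermodynamics from a measured per-temperature binding-constant series, and
binding parameters recovered from simulated three-concentration titrations:

```r
library(quenchbind)

vh <- vant_hoff_fit(c(288, 298, 308), c(3.90, 2.77, 2.06) * 1e4)
print(thermo_report(vh))
#> <thermo_report> dH = -23.55 kJ/mol, dS = 6.10 J/(mol K) [enthalpy-driven: hydrogen bond / van der Waals]
#>   T = 288 K: dG = -25.30 kJ/mol, T*dS = 1.76 kJ/mol
#>   T = 298 K: dG = -25.36 kJ/mol, T*dS = 1.82 kJ/mol
#>   T = 308 K: dG = -25.42 kJ/mol, T*dS = 1.88 kJ/mol

cfg <- sim_config(k_b_true = 7e4, n_sites_true = 3, noise_rel = 0)
res <- idf_analysis(simulate_titration(cfg)$series)
print(res$fit)
#> <scatchard_fit> K_b = 6.886e+04 1/M, n = 3.031, r2 = 0.9993 [non_cooperative_linear] (10 points)

kb_from_score(c(-6.7, -6.6, -6.4), temperature = 300) / 1e4
#> [1] 7.61 6.43 4.60
```

The thermodynamic block reads: binding is exothermic (ΔH < 0) with a small
favourable entropy, so ΔG ≈ −25 kJ/mol is nearly temperature-independent
and the association is enthalpy-driven — the signature of hydrogen bonding
and van der Waals contacts. The Scatchard block recovers the simulator's
ground truth (three equivalent sites, K_b = 7×10⁴ M⁻¹) to within 2%, with
the linear plot flagging non-cooperative binding. The docking conversion
maps energy scores in kcal/mol to binding constants on the 10⁴ M⁻¹ scale.

A whole study can also be driven from one YAML config with
`run_pipeline()`, which gates stages on available inputs (titrations by
temperature, titrations by protein concentration, decay traces, CD, docking
scores) and emits a machine-readable JSON report (`write_report()`).

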