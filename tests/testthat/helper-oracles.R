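# Independent oracles used across the suite.

# Bisection solver for the free-ligand mass balance: finds Lf such that
# Lf + n*Kb*Lf/(1 + Kb*Lf) * P - Ltot = 0 on [0, Ltot]. Shares no code with
# solve_free_ligand (which uses the closed-form quadratic root).
bisect_free_ligand <- function(ligand_total, protein_total, k_b, n_sites,
                               tol = 1e-15, max_iter = 200) {
  if (ligand_total == 0) return(0)
  resid <- function(lf) {
    lf + n_sites * k_b * lf / (1 + k_b * lf) * protein_total - ligand_total
  }
  lo <- 0
  hi <- ligand_total
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < tol * ligand_total) break
  }
  (lo + hi) / 2
}

# Exact ground-truth (sigma_nu, ligand_free) pair at a quench level for the
# linear signal-transduction model dF = 100 * q_max * nu / n.
truth_at_level <- function(level, k_b, n_sites, q_max) {
  nu <- level / 100 * n_sites / q_max
  list(sigma_nu = nu, ligand_free = nu / (k_b * (n_sites - nu)))
}

# Noiseless titration series satisfying F0/F = 1 + ksv * L exactly.
make_sv_series <- function(ksv, ligand = seq(0, 12e-6, by = 1e-6), f0 = 1000,
                           protein_conc = 4e-6, temperature = 298) {
  titration_series(
    ligand_total = ligand,
    intensity = f0 / (1 + ksv * ligand),
    protein_conc = protein_conc,
    temperature = temperature
  )
}

sv_fit_stub <- function(k_sv, temperature) {
  structure(list(k_sv = k_sv, temperature = temperature),
            class = "stern_volmer_fit")
}
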