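test_that("free-ligand solver handles the no-binding limits", {
  lt <- seq(0, 3e-5, by = 1e-6)
  expect_equal(solve_free_ligand(lt, 0, 7e4, 3), lt)
  expect_equal(solve_free_ligand(lt, 4e-6, 0, 3), lt)
  expect_equal(solve_free_ligand(lt, 4e-6, 7e4, 0), lt)
  expect_equal(solve_free_ligand(0, 4e-6, 7e4, 3), 0)
})

test_that("free-ligand solver matches the bisection oracle on its reference case", {
  lf <- solve_free_ligand(1e-5, 4e-6, 7e4, 3)
  expect_equal(lf, 6.3196e-6, tolerance = 1e-4)
  expect_equal(lf, bisect_free_ligand(1e-5, 4e-6, 7e4, 3), tolerance = 1e-10)
})

test_that("free-ligand solver agrees with bisection across a randomized grid", {
  set.seed(42)
  lts <- 10^runif(10, -7, -4)
  pts <- 10^runif(10, -7, -4.5)
  kbs <- 10^runif(10, 3, 6)
  for (n in c(1, 2, 3)) {
    for (lt in lts) for (pt in pts) for (kb in kbs[1:3]) {
      lf <- solve_free_ligand(lt, pt, kb, n)
      expect_equal(lf, bisect_free_ligand(lt, pt, kb, n),
                   tolerance = 1e-10)
      expect_true(lf >= 0 && lf <= lt)
    }
  }
})

test_that("free ligand is monotone in totals, affinity, and site count", {
  lt <- seq(1e-6, 3e-5, by = 1e-6)
  lf <- solve_free_ligand(lt, 4e-6, 7e4, 3)
  expect_true(all(diff(lf) > 0))
  lf_p <- vapply(c(1, 2, 4, 8, 16) * 1e-6,
                 function(p) solve_free_ligand(1e-5, p, 7e4, 3), numeric(1))
  expect_true(all(diff(lf_p) < 0))
  lf_k <- vapply(10^seq(3, 6, by = 0.5),
                 function(k) solve_free_ligand(1e-5, 4e-6, k, 3), numeric(1))
  expect_true(all(diff(lf_k) < 0))
  lf_n <- vapply(1:4, function(n) solve_free_ligand(1e-5, 4e-6, 7e4, n),
                 numeric(1))
  expect_true(all(diff(lf_n) < 0))
})

test_that("binding density follows the isotherm", {
  expect_equal(binding_density(2e5, 3, 1 / 2e5), 1.5)  # half saturation
  expect_equal(binding_density(7e4, 3, 0), 0)
  expect_equal(binding_density(7e4, 3, 6.3196e-6), 0.92009, tolerance = 1e-4)
  expect_true(binding_density(7e4, 3, 1) < 3)  # bounded by n at saturation
})

test_that("ground truth satisfies mass conservation exactly", {
  cfg <- sim_config(noise_rel = 0.01, seed = 11)
  gt <- simulate_titration(cfg)$ground_truth$records
  resid <- gt$ligand_total - gt$ligand_free - gt$sigma_nu * gt$protein_conc
  nonzero <- gt$ligand_total > 0
  expect_true(all(abs(resid[nonzero]) / gt$ligand_total[nonzero] < 1e-12))
})

test_that("titration simulation is deterministic and stream-stable per protein", {
  cfg <- sim_config(noise_rel = 0.02, seed = 7)
  a <- simulate_titration(cfg)
  b <- simulate_titration(cfg)
  expect_identical(a, b)
  # appending a protein concentration must not perturb existing series
  cfg2 <- sim_config(noise_rel = 0.02, seed = 7,
                     protein_concs = c(2e-6, 4e-6, 8e-6, 16e-6))
  c3 <- simulate_titration(cfg2)
  for (i in 1:3) {
    expect_identical(a$series[[i]]$intensity, c3$series[[i]]$intensity)
  }
})

test_that("single-site full-quenching generator reduces to the Stern-Volmer law in free ligand", {
  cfg <- sim_config(k_b_true = 5e4, n_sites_true = 1, q_max = 1,
                    protein_concs = 4e-6,
                    ligand_grid = seq(0, 1.5e-5, by = 1e-6), noise_rel = 0)
  out <- simulate_titration(cfg)
  s <- out$series[[1]]
  gt <- out$ground_truth$records
  expect_equal(s$intensity[1] / s$intensity,
               1 + 5e4 * gt$ligand_free, tolerance = 1e-12)
})

test_that("zero transduction leaves the signal at F0", {
  cfg <- sim_config(q_max = 1e-12, noise_rel = 0, f0 = 123)
  out <- simulate_titration(cfg)
  for (s in out$series) {
    expect_equal(s$intensity, rep(123, length(s$intensity)),
                 tolerance = 1e-9)
  }
})

test_that("Ka-at-temperature inverts the van't Hoff relation", {
  expect_equal(ka_at_temperature(0, 0, 298), 1)
  expect_equal(ka_at_temperature(-23540, 6.1, 288), 3.88e4, tolerance = 0.01)
  temps <- c(288, 298, 308)
  fit <- vant_hoff_fit(temps, ka_at_temperature(-1.7e4, 22, temps))
  expect_equal(fit$delta_h, -1.7e4, tolerance = 1e-9)
  expect_equal(fit$delta_s, 22, tolerance = 1e-9)
})

test_that("decay simulation produces exact exponential expectations and is seeded", {
  tr <- simulate_decay(1, 3, time_range = 25, n_bins = 256,
                       peak_counts = 1e4, poisson_noise = FALSE)
  expect_equal(tr$counts, 1e4 * exp(-tr$time / 3), tolerance = 1e-12)
  a <- simulate_decay(c(0.5, 0.5), c(1, 3), seed = 5)
  b <- simulate_decay(c(0.5, 0.5), c(1, 3), seed = 5)
  expect_identical(a, b)
  expect_true(all(a$counts == floor(a$counts)))
  expect_error(simulate_decay(c(1, 1), 3), "equal length")
})
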