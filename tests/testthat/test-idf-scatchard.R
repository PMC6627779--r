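test_that("quench curve reproduces noiseless knots exactly and respects its range", {
  cfg <- sim_config(noise_rel = 0)
  s <- simulate_titration(cfg)$series[[2]]
  cv <- build_quench_curve(s)
  expect_false(cv$denoised)
  expect_equal(predict(cv, cv$knots$delta_f), cv$knots$ligand_total,
               tolerance = 1e-12)
  # mid-level query falls between neighbouring knot abscissae
  mid <- (cv$knots$delta_f[4] + cv$knots$delta_f[5]) / 2
  lt <- predict(cv, mid)
  expect_true(lt > cv$knots$ligand_total[4] && lt < cv$knots$ligand_total[5])
  expect_error(predict(cv, cv$range[2] + 1), "range")
  expect_error(predict(cv, cv$range[1] - 1), "range")
})

test_that("non-monotone quenching beyond tolerance is an error", {
  s <- titration_series(seq(0, 9e-6, 1e-6),
                        c(1000, 950, 900, 980, 850, 820, 800, 780, 770, 760),
                        4e-6, 298)
  expect_error(build_quench_curve(s, denoise = FALSE), "not monotone")
  expect_error(build_quench_curve(
    titration_series(c(0, 1e-6, 2e-6), c(10, 9, 8), 4e-6, 298)),
    "at least 5")
})

test_that("IDF extraction solves the hand-computable two-curve case", {
  # linear quench maps through the origin: curve A reaches dF = 50 at 5 uM,
  # curve B at 8 uM, so the level-50 line L_tot = L_free + sigma_nu * P has
  # slope (8-5)/(4-2) uM/uM = 1.5 and intercept 5 - 1.5*2 = 2 uM
  lig_a <- seq(0, 8e-6, length.out = 11)
  lig_b <- seq(0, 1.2e-5, length.out = 11)
  f0 <- 1000
  a <- titration_series(lig_a, f0 * (1 - lig_a / 5e-6 * 0.5), 2e-6, 288)
  b <- titration_series(lig_b, f0 * (1 - lig_b / 8e-6 * 0.5), 4e-6, 288)
  curves <- list(build_quench_curve(a), build_quench_curve(b))
  pts <- idf_extract(curves, levels = 50)
  expect_equal(pts$sigma_nu, 1.5, tolerance = 1e-9)
  expect_equal(pts$ligand_free, 2e-6, tolerance = 1e-9)
  expect_equal(pts$n_curves_used, 2L)
})

test_that("IDF extraction demands at least two distinct protein concentrations", {
  cfg <- sim_config(noise_rel = 0)
  series <- simulate_titration(cfg)$series
  c1 <- build_quench_curve(series[[1]])
  expect_error(idf_extract(list(c1)), "at least 2")
  expect_error(idf_extract(list(c1, c1)), "distinct")
})

test_that("IDF points match generator ground truth on noiseless curves", {
  cfg <- sim_config(k_b_true = 7e4, n_sites_true = 3, q_max = 0.8,
                    noise_rel = 0)
  sim <- simulate_titration(cfg)
  curves <- lapply(sim$series, build_quench_curve)
  pts <- idf_extract(curves)
  pts <- pts[!pts$excluded, ]
  for (i in seq_len(nrow(pts))) {
    tr <- truth_at_level(pts$delta_f_level[i], 7e4, 3, 0.8)
    expect_equal(pts$sigma_nu[i], tr$sigma_nu, tolerance = 0.01)
    expect_equal(pts$ligand_free[i], tr$ligand_free, tolerance = 0.01)
  }
})

test_that("extracted points respect mass conservation on every curve", {
  cfg <- sim_config(noise_rel = 0)
  sim <- simulate_titration(cfg)
  curves <- lapply(sim$series, build_quench_curve)
  pts <- idf_extract(curves)
  pts <- pts[!pts$excluded, ]
  for (i in seq_len(nrow(pts))) {
    for (cv in curves) {
      lt <- predict(cv, pts$delta_f_level[i])
      resid <- abs(lt - pts$ligand_free[i] -
                     pts$sigma_nu[i] * cv$protein_conc) / lt
      expect_lt(resid, 0.02)
    }
  }
  # binding density grows with the quench level
  expect_true(all(diff(pts$sigma_nu) > 0))
})

test_that("Scatchard regression recovers a hand-built exact line", {
  # slope -1e5, intercept 2e5: Kb = 1e5, n = 2
  nu <- c(1, 1.5, 0.5)
  pts <- data.frame(sigma_nu = nu, ligand_free = nu / (2e5 - 1e5 * nu))
  fit <- scatchard_fit(pts)
  expect_equal(fit$k_b, 1e5, tolerance = 1e-9)
  expect_equal(fit$n_sites, 2, tolerance = 1e-9)
  expect_identical(fit$cooperativity_flag, "non_cooperative_linear")
})

test_that("Scatchard rejects degenerate and non-saturable input", {
  expect_error(scatchard_fit(
    data.frame(sigma_nu = c(1, 1, 1), ligand_free = c(1e-6, 2e-6, 3e-6))),
    "no saturable binding")
  expect_error(scatchard_fit(
    data.frame(sigma_nu = c(1, 2), ligand_free = c(1e-6, 2e-6))),
    "at least 3")
})

test_that("generated Scatchard points lie exactly on the isotherm line", {
  lf <- seq(1e-6, 2e-5, length.out = 8)
  nu <- binding_density(7e4, 3, lf)
  y <- nu / lf
  fit <- stats::lm(y ~ nu)
  expect_equal(unname(coef(fit)[2]), -7e4, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[1]), 3 * 7e4, tolerance = 1e-9)
})

test_that("full noiseless pipeline recovers the generating constants", {
  cfg <- sim_config(k_b_true = 7e4, n_sites_true = 3, noise_rel = 0)
  res <- idf_analysis(simulate_titration(cfg)$series)
  expect_equal(res$fit$k_b, 7e4, tolerance = 0.02)
  expect_equal(res$fit$n_sites, 3, tolerance = 0.05 / 3)
  expect_identical(res$fit$cooperativity_flag, "non_cooperative_linear")
})

test_that("denoised curves stay close to the clean signal under noise", {
  cfg0 <- sim_config(noise_rel = 0, seed = 2)
  cfg1 <- sim_config(noise_rel = 0.01, seed = 2)
  clean <- build_quench_curve(simulate_titration(cfg0)$series[[2]])
  noisy <- build_quench_curve(simulate_titration(cfg1)$series[[2]],
                              noise_tolerance = 6)
  expect_true(noisy$denoised)
  lv <- seq(max(clean$range[1], noisy$range[1]) + 1,
            min(clean$range[2], noisy$range[2]) - 1, length.out = 7)
  rel <- abs(predict(noisy, lv) - predict(clean, lv)) / predict(clean, lv)
  expect_lt(median(rel), 0.1)
})
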