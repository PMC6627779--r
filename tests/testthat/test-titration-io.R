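test_that("inner-filter correction matches direct evaluation and its algebraic properties", {
  expect_equal(correct_inner_filter(100, 0, 0), 100)
  expect_equal(correct_inner_filter(100, 0.1, 0.1), 100 * 10^0.1)
  expect_equal(correct_inner_filter(50, 0.2, 0), 50 * 10^0.1)

  # monotone increasing in each absorbance; identity iff A_ex + A_em = 0
  a <- seq(0, 0.5, by = 0.05)
  f <- correct_inner_filter(rep(100, length(a)), a, 0.1)
  expect_true(all(diff(f) > 0))
  expect_true(all(correct_inner_filter(rep(7, 20), runif(20, 0.01, 1), 0) > 7))
  expect_error(correct_inner_filter(100, -0.1, 0), "non-negative")
})

test_that("quench percentage follows its defining formula exactly", {
  expect_equal(quench_percent(100, 100), 0)
  expect_equal(quench_percent(100, 75), 25)
  expect_equal(quench_percent(200, 90), 55)
  # identity dF(f0, f0*(1-x)) = 100x
  for (x in seq(0, 1, by = 0.125)) {
    expect_equal(quench_percent(80, 80 * (1 - x)), 100 * x)
  }
  expect_error(quench_percent(0, 50), "f0")
})

test_that("Beer-Lambert concentrations come out in mol/L", {
  expect_equal(concentration_from_absorbance(0, 16500), 0)
  expect_equal(concentration_from_absorbance(0.165, 16500, 1), 1e-5)
  expect_equal(concentration_from_absorbance(0.389, 38915, 1), 0.389 / 38915)
  expect_error(concentration_from_absorbance(0.1, 0), "epsilon")
  expect_error(concentration_from_absorbance(0.1, 16500, 0), "path_length")
})

test_that("titration series validates its invariants", {
  expect_error(
    titration_series(c(0, 2e-6, 1e-6), c(3, 2, 1), 4e-6, 298),
    "non-decreasing")
  expect_error(
    titration_series(c(0, 1e-6), c(3, -1), 4e-6, 298), "positive")
  expect_error(
    titration_series(c(0, 1e-6), c(3, 2, 1), 4e-6, 298), "length")
  s <- titration_series(c(0, 1e-6, 2e-6), c(3, 2.5, 2), 4e-6, 298)
  expect_false(s$inner_filter_corrected)
})

test_that("absorbance columns trigger inner-filter correction at construction", {
  s <- titration_series(c(0, 1e-6), c(100, 90), 4e-6, 298,
                        absorbance_ex = c(0.1, 0.1),
                        absorbance_em = c(0.1, 0.1))
  expect_true(s$inner_filter_corrected)
  expect_equal(s$intensity, c(100, 90) * 10^0.1)
})

test_that("read/write round-trip preserves every field bit-identically", {
  s <- titration_series(
    ligand_total = seq(0, 15e-6, by = 1e-6),
    intensity = 1000 / (1 + 3.3e4 * seq(0, 15e-6, by = 1e-6)),
    protein_conc = 4e-6, temperature = 288)
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration_table(s, path)
  s2 <- read_titration_table(path)
  expect_identical(s2$ligand_total, s$ligand_total)
  expect_identical(s2$intensity, s$intensity)
  expect_identical(s2$protein_conc, s$protein_conc)
  expect_identical(s2$temperature, s$temperature)
  expect_equal(length(s2$ligand_total), 16L)
  # second round trip is a fixed point
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_titration_table(s2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("micromolar dialect units are converted to mol/L on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# protein_conc=4", "# temperature=298", "# units=uM",
    "ligand_total,intensity",
    "0,1000", "1,950", "2,910"), path)
  s <- read_titration_table(path)
  expect_equal(s$ligand_total, c(0, 1e-6, 2e-6))
  expect_equal(s$protein_conc, 4e-6)
})

test_that("schema errors name the missing piece", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# protein_conc=4e-6", "# temperature=298",
               "ligand_total,signal", "0,1000", "1e-6,950"), path)
  expect_error(read_titration_table(path), "intensity")
  writeLines(c("# temperature=298", "ligand_total,intensity",
               "0,1000", "1e-6,950"), path)
  expect_error(read_titration_table(path), "protein_conc")
  expect_error(read_titration_table("no/such/file.csv"), "not found")
})

test_that("re-reading an inner-filter-corrected file does not correct twice", {
  s <- titration_series(c(0, 1e-6, 2e-6), c(100, 95, 90), 4e-6, 298,
                        absorbance_ex = rep(0.05, 3),
                        absorbance_em = rep(0.02, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration_table(s, path)
  s2 <- read_titration_table(path)
  expect_true(s2$inner_filter_corrected)
  expect_identical(s2$intensity, s$intensity)
})
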