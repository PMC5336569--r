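test_that("noise-free null spectra are identical within a sex", {
  d <- small_design()
  tr <- one_truth(norm_class = "null")
  s <- simulate_spectra(d, tr, nuisance_off(), seed = 1)
  f <- which(s$meta$sex == "female")
  for (i in f[-1])
    expect_equal(s$intensities[i, ], s$intensities[f[1], ])
})

test_that("a linear_down metabolite decreases monotonically with temperature", {
  d <- simulation_design(c(12, 15.5, 18, 20, 22, 25, 27, 29.5, 31, 32),
                         replicates_per_cell = 2,
                         ppm_grid = c(min = -0.1, max = 9.6, step = 0.005))
  tr <- one_truth(norm_class = "linear_down", effect_size = -0.5)
  s <- simulate_spectra(d, tr, nuisance_off(), seed = 1)
  idx <- which(s$ppm >= 2.99 & s$ppm <= 3.01)
  f <- s$meta$sex == "female"
  area <- tapply(rowSums(s$intensities[f, idx, drop = FALSE]),
                 s$meta$temperature[f], mean)
  expect_true(all(diff(area[order(as.numeric(names(area)))]) < 0))
  expect_equal(unname(stats::cor(as.numeric(names(area)), area,
                                 method = "spearman")), -1)
})

test_that("same seed reproduces spectra bitwise, different seeds differ", {
  d <- small_design(reps = 2)
  tr <- default_truths_quiet()
  s1 <- simulate_spectra(d, tr, nuisance_control(), seed = 42)
  s2 <- simulate_spectra(d, tr, nuisance_control(), seed = 42)
  s3 <- simulate_spectra(d, tr, nuisance_control(), seed = 43)
  expect_identical(s1$intensities, s2$intensities)
  expect_false(identical(s1$intensities, s3$intensities))
})

test_that("simulation rejects duplicate names and oversized jitter", {
  d <- small_design()
  tr <- dplyr::bind_rows(one_truth(), one_truth())
  expect_error(simulate_spectra(d, tr, nuisance_off(), seed = 1),
               "overlapping definition")
  expect_error(simulate_spectra(d, one_truth(),
                                nuisance_control(jitter_ppm = 0.5), seed = 1),
               "jitter")
})

test_that("noise-free total area follows the closed-form bookkeeping", {
  # step 0.001 so the discrete Lorentzian sums approximate line areas
  d <- small_design(reps = 2, step = 0.001)
  tr <- one_truth(norm_class = "ushape_down", effect_size = -0.5)
  s <- simulate_spectra(d, tr, nuisance_off(), seed = 1)
  tot <- rowSums(s$intensities) * d$ppm_grid[["step"]]
  # two metabolite lines (area modified by condition), a background pool
  # absorbing exactly the planted deficit, and the TSP line: the total is
  # the conserved constant pool + background + TSP
  expected <- 2 * 1 + 2 * sum(tr$baseline) + 3
  expect_equal(unname(tot), rep(expected, length(tot)), tolerance = 1e-2)
  expect_lt(stats::sd(tot) / mean(tot), 1e-3)
})

test_that("truth table maps classes to expected signs", {
  tr <- dplyr::bind_rows(
    one_truth("a", norm_class = "linear_down", effect_size = -0.5),
    one_truth("b", norm_class = "ushape_down", effect_size = -0.5),
    one_truth("c", norm_class = "null"),
    one_truth("d", norm_class = "sex_dimorphic",
              sex_effect = list(list(type = "constant", delta = 0.5))))
  tt <- truth_table(tr)
  expect_equal(tt$expected_linear, c("-", "0", "0", "0"))
  expect_equal(tt$expected_ushape, c("0", "-", "0", "0"))
  expect_equal(tt$expected_sexdiff, c("0", "0", "0", "+"))
  bad <- one_truth()
  bad$norm_class <- "quadratic"
  expect_error(truth_table(bad), "unknown norm_class")
})

test_that("spectrum sets round-trip through the TSV/CSV dialect", {
  d <- small_design(reps = 2, step = 0.01)
  s <- simulate_spectra(d, one_truth(), nuisance_off(), seed = 5)
  path <- file.path(withr::local_tempdir(), "spec")
  write_spectra(s, path, sidecar = list(seed = 5))
  r <- read_spectra(path)
  expect_equal(r$ppm, s$ppm)
  expect_equal(unname(r$intensities), unname(s$intensities),
               tolerance = 1e-12)
  expect_equal(r$meta$temperature, s$meta$temperature)
})
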