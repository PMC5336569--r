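lorentz <- function(ppm, center, area, fwhm = 0.002) {
  g <- fwhm / 2
  (area / pi) * g / ((ppm - center)^2 + g^2)
}

test_that("TSP referencing shifts the maximum to the target bin", {
  ppm <- rev(seq(-0.1, 9.6, by = 0.001))
  y <- lorentz(ppm, -0.017, 3)
  s <- new_spectrum(ppm, y)
  expect_equal(reference_to_tsp(s)$intensity, s$intensity)
  y2 <- lorentz(ppm, 0.050, 3)
  r <- reference_to_tsp(new_spectrum(ppm, y2))
  win <- which(r$ppm >= -0.25 & r$ppm <= 0.25)
  expect_equal(r$ppm[win][which.max(r$intensity[win])], -0.017)
  # a flat window carries no peak
  expect_error(reference_to_tsp(new_spectrum(ppm, rep(1, length(ppm)))),
               "prominence")
})

test_that("alignment recovers planted integer-bin shifts against the median", {
  ppm <- rev(seq(0, 10, by = 0.01))
  base <- lorentz(ppm, 5, 1, fwhm = 0.05) + lorentz(ppm, 2, 2, fwhm = 0.05)
  m <- rbind(base, base, base, base)
  m[4, ] <- c(m[4, -(1:3)], rep(m[4, length(ppm)], 3))  # +3-bin offset
  set <- toy_set(m, ppm = ppm)
  al <- align_set(set, max_shift = 0.1)
  expect_equal(unname(al$intensities[4, 10:990]),
               unname(base[10:990]), tolerance = 1e-10)
  # already aligned spectra are untouched
  set2 <- toy_set(rbind(base, base, base), ppm = ppm)
  expect_equal(align_set(set2, max_shift = 0.1)$intensities[1, ],
               set2$intensities[1, ])
})

test_that("alignment shifts are capped at max_shift with a warning", {
  ppm <- rev(seq(0, 10, by = 0.01))
  base <- lorentz(ppm, 5, 1, fwhm = 0.05)
  planted <- 6L
  m <- rbind(base, base, base, base, base)
  m[5, ] <- shift_fill_test(base, planted)
  set <- toy_set(m, ppm = ppm)
  expect_warning(al <- align_set(set, max_shift = 0.03, passes = 1), "cap")
  # residual shift equals planted minus the 3-bin cap
  expect_equal(unname(al$intensities[5, 20:980]),
               unname(shift_fill_test(base, planted - 3L)[20:980]),
               tolerance = 1e-10)
  expect_error(align_set(toy_set(m, ppm = ppm),
                         segments = list(c(5, 5.03)), max_shift = 0.03),
               "narrower")
})

test_that("trimming removes exactly the closed water and edge windows", {
  ppm <- rev(seq(-0.1, 9.6, by = 0.005))
  s <- new_spectrum(ppm, seq_along(ppm))
  tr <- trim_spectrum(s)
  expect_false(any(tr$ppm >= 4.67 & tr$ppm <= 4.85))
  expect_false(any(tr$ppm < 0.5 | tr$ppm > 9.5))
  expect_true(4.665 %in% round(tr$ppm, 3))
  expect_true(4.855 %in% round(tr$ppm, 3))
  expect_true(0.55 %in% round(tr$ppm, 3))
  expect_false(0.4 %in% round(tr$ppm, 3))
  water_only <- new_spectrum(rev(seq(4.68, 4.84, by = 0.005)),
                             rep(1, length(seq(4.68, 4.84, by = 0.005))))
  expect_error(trim_spectrum(water_only), "every grid point")
})

test_that("total-intensity normalization is exact, scale-invariant and idempotent", {
  set <- toy_set(rbind(c(1, 3), c(2, 2)), ppm = c(2, 1))
  n1 <- normalize_total(set)
  expect_equal(unname(n1$intensities[1, ]), c(0.25, 0.75))
  set_scaled <- toy_set(10 * set$intensities, ppm = c(2, 1))
  expect_equal(normalize_total(set_scaled)$intensities, n1$intensities)
  # idempotence on values (a fresh set with already-normalized rows)
  set_again <- toy_set(n1$intensities, ppm = c(2, 1))
  expect_equal(normalize_total(set_again)$intensities, n1$intensities,
               tolerance = 1e-12)
  expect_error(normalize_total(toy_set(rbind(c(0, 0)), ppm = c(2, 1))),
               "non-positive")
})

test_that("pipeline steps refuse to run twice and keep an append-only log", {
  set <- toy_set(rbind(c(1, 3), c(2, 2)), ppm = c(2, 1))
  n1 <- normalize_total(set)
  expect_error(normalize_total(n1), "already been applied")
  expect_equal(n1$log, c("normalize(total)"))
})

test_that("feature matrices bin half-open with the boundary in the higher-ppm bin", {
  ppm <- c(4, 3, 2, 1)
  set <- toy_set(rbind(c(2, 4, 6, 8)), meta = tibble::tibble(
    sample_id = "s1", sex = "female", temperature = 20, replicate = 1),
    ppm = ppm)
  fm <- to_feature_matrix(set)
  expect_equal(dim(fm$values), c(1L, 4L))
  b <- to_feature_matrix(set, bin_width = 2)
  # bins (2,4] and (0,2]: ppm 4,3 -> mean 3; ppm 2 joins the higher bin
  expect_equal(unname(b$values[1, ]), c(mean(c(2, 4, 6)), 8))
  expect_error(to_feature_matrix(set, bin_width = 0.5), "grid step")
})

test_that("Pareto scaling matches hand arithmetic and handles zero variance", {
  m <- new_feature_matrix(cbind(c(0, 2), c(5, 5)), ppm = c(2, 1),
                          meta = tibble::tibble(sample_id = c("a", "b")))
  ps <- pareto_scale(m, centered = TRUE)
  expect_equal(unname(ps$values[, 1]), c(-1, 1) / 2^0.25, tolerance = 1e-12)
  expect_equal(unname(ps$values[, 2]), c(0, 0))
  expect_equal(ps$scaling, "pareto_centered")
  m2 <- new_feature_matrix(cbind(c(0, 2), c(5, 5)), ppm = c(2, 1),
                           meta = tibble::tibble(sample_id = c("a", "b")))
  expect_warning(pu <- pareto_scale(m2, centered = FALSE), "zero-variance")
  expect_equal(unname(pu$values[, 2]), c(5, 5))  # left unscaled
  expect_gt(mean(pu$values[, 1]), 0)             # no centering applied
  expect_equal(pu$scaling, "pareto_uncentered")
  one_row <- new_feature_matrix(rbind(c(1, 2)), ppm = c(2, 1),
                                meta = tibble::tibble(sample_id = "a"))
  expect_error(pareto_scale(one_row), ">= 2 rows")
})

test_that("alignment preserves totals up to the edge-fill contribution", {
  ppm <- rev(seq(0, 10, by = 0.01))
  base <- lorentz(ppm, 5, 1, fwhm = 0.05)
  m <- rbind(base, base, base, shift_fill_test(base, 4L))
  set <- toy_set(m, ppm = ppm)
  al <- align_set(set, max_shift = 0.1)
  # the peak sits mid-spectrum, so edge fill moves only near-baseline
  # values; the total may change by at most the filled edge contribution
  edge_bound <- 10 * max(c(head(base, 10), tail(base, 10)))
  expect_lt(max(abs(unname(rowSums(al$intensities)) - sum(base))),
            edge_bound + 1e-12)
})
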