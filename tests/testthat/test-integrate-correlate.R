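test_that("the bundled assignment table loads 30 validated definitions", {
  defs <- load_metabolite_definitions()
  expect_equal(nrow(defs), 30)
  glu <- defs[defs$name == "Glucose", ]
  expect_equal(glu$shifts[[1]], 5.21)
  expect_equal(c(glu$range_high, glu$range_low), c(5.213, 5.207))
  amp <- defs[defs$name == "AMP", ]
  expect_equal(amp$shifts[[1]], c(8.60, 8.25, 6.13))
  expect_equal(c(amp$range_high, amp$range_low), c(8.609, 8.584))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,shifts,range_high,range_low", "X,1.0,0.9,1.1"), bad)
  expect_error(load_metabolite_definitions(bad), "inverted")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,shifts,range_high,range_low",
               "X,1.0,1.1,0.9", "X,2.0,2.1,1.9"), dup)
  expect_error(load_metabolite_definitions(dup), "duplicate")
})

test_that("integration sums the closed range and matches the Lorentzian integral", {
  ppm <- rev(seq(-0.1, 9.6, by = 0.001))
  zero <- toy_set(rbind(rep(0, length(ppm)), rep(0, length(ppm))), ppm = ppm)
  defs <- load_metabolite_definitions()
  vals <- integrate_metabolites(zero, defs)
  expect_true(all(as.matrix(vals[defs$name]) == 0))
  # unit-area line centred in a window much wider than its FWHM
  y <- stats::dcauchy(ppm, location = 3, scale = 0.001)
  set <- toy_set(rbind(y, y), ppm = ppm)
  wide <- tibble::tibble(name = "wide", shifts = list(3),
                         range_high = 3.05, range_low = 2.95)
  out <- integrate_metabolites(set, wide)
  expect_equal(unname(out$wide[1]) * 0.001, 1, tolerance = 0.02)
  outside <- tibble::tibble(name = "water_met", shifts = list(4.7),
                            range_high = 4.76, range_low = 4.70)
  trimmed <- toy_set(rbind(y, y), ppm = ppm) |>
    trim_set(keep = c(0.5, 9.6))
  expect_error(integrate_metabolites(trimmed, outside), "water_met")
})

test_that("integrated intensities are dilution-invariant after normalization", {
  d <- small_design(reps = 2)
  tr <- one_truth(norm_class = "linear_down", effect_size = -0.5)
  s <- simulate_spectra(d, tr, nuisance_control(0, 0.3, 0), seed = 2)
  set <- s |> trim_set(keep = c(0.5, 9.6)) |> normalize_total()
  ints <- integrate_metabolites(set, tr)
  same_cell <- ints[ints$sex == "female" & ints$temperature == 22, ]
  expect_lt(diff(range(same_cell$TestMet)), 1e-9)
})

test_that("correlation screening returns exact r for constructed targets", {
  d <- small_design(reps = 4)
  tr <- one_truth(norm_class = "linear_down", effect_size = -0.5)
  s <- simulate_spectra(d, tr, nuisance_off(), seed = 3)
  # noiseless, undiluted construction: intensities are exactly linear in
  # temperature before normalization
  set <- trim_set(s, keep = c(0.5, 9.6))
  ints <- integrate_metabolites(set, tr)
  res <- correlate_with_target(ints, set$meta$temperature, tr, set,
                               target = "linear_prior",
                               sex_context = "both")
  expect_equal(res$r, -1, tolerance = 1e-9)
  expect_lt(res$p, 1e-10)
  expect_true(res$verified)
  # intensity column equal to the target itself
  ints$TestMet <- as.numeric(set$meta$temperature)
  res2 <- correlate_with_target(ints, set$meta$temperature, tr, set)
  expect_equal(res2$r, 1, tolerance = 1e-12)
  ints$TestMet <- 1
  expect_warning(res3 <- correlate_with_target(ints, set$meta$temperature,
                                               tr, set),
                 "zero-variance")
  expect_false(res3$tested)
  expect_true(is.na(res3$p))
})

test_that("step-down correction uses denominators starting at the assumed family size", {
  mk <- function(p) tibble::tibble(
    metabolite = paste0("m", seq_along(p)), target = "linear_prior",
    sex_context = "both", r = 0.5, p = p, n = 50, tested = TRUE,
    verified = TRUE)
  r1 <- holm_significance(mk(c(0.0004, 0.9)), assumed_m = 100)
  expect_equal(r1$significant, c(TRUE, FALSE))
  r2 <- holm_significance(mk(c(0.0006, 0.9)), assumed_m = 100)
  expect_equal(r2$significant, c(FALSE, FALSE))
  r3 <- holm_significance(mk(rep(1, 8)), assumed_m = 100)
  expect_false(any(r3$significant))
  expect_error(holm_significance(mk(rep(0.01, 8)), assumed_m = 5),
               "assumed_m")
})

test_that("step-down flags match brute force and reduce to textbook Holm", {
  set.seed(19)
  for (i in 1:200) {
    k <- sample(2:12, 1)
    p <- stats::runif(k)^sample(1:4, 1)
    m <- sample(k:110, 1)
    res <- holm_significance(
      tibble::tibble(metabolite = paste0("m", 1:k),
                     target = "linear_prior", sex_context = "both",
                     r = 0, p = p, n = 10, tested = TRUE, verified = TRUE),
      assumed_m = m)
    expect_equal(res$significant, oracle_holm(p, m))
    # with assumed_m = k the procedure is plain Holm
    res_k <- holm_significance(
      tibble::tibble(metabolite = paste0("m", 1:k),
                     target = "linear_prior", sex_context = "both",
                     r = 0, p = p, n = 10, tested = TRUE, verified = TRUE),
      assumed_m = k)
    expect_equal(res_k$significant,
                 stats::p.adjust(p, method = "holm") <= 0.05)
  }
})

test_that("families are corrected separately per target and sex", {
  res <- tibble::tibble(
    metabolite = c("a", "a", "b", "b"),
    target = c("linear_prior", "ushape_prior", "linear_prior",
               "ushape_prior"),
    sex_context = "female", r = c(-0.9, 0.1, 0.2, 0.1),
    p = c(1e-6, 0.5, 0.6, 0.7), n = 50, tested = TRUE, verified = TRUE)
  out <- holm_significance(res, assumed_m = 100)
  expect_equal(out$significant[out$metabolite == "a" &
                                 out$target == "linear_prior"], TRUE)
  expect_equal(sum(out$significant), 1)
})

test_that("classification combines shape families with sign consistency", {
  mk <- function(met, target, sex, r, sig) tibble::tibble(
    metabolite = met, target = target, sex_context = sex, r = r,
    p = ifelse(sig, 1e-6, 0.5), n = 50, tested = TRUE, verified = TRUE,
    significant = sig)
  res <- dplyr::bind_rows(
    mk("proline", "linear_component", "female", -0.9, TRUE),
    mk("proline", "linear_prior", "female", -0.95, TRUE),
    mk("proline", "ushape_component", "female", 0.1, FALSE),
    mk("proline", "ushape_prior", "female", 0.1, FALSE),
    mk("nad", "ushape_component", "female", -0.8, TRUE),
    mk("nad", "ushape_prior", "female", -0.85, TRUE),
    mk("nad", "linear_component", "female", 0, FALSE),
    mk("nad", "linear_prior", "female", 0, FALSE),
    mk("quiet", "linear_component", "female", 0.1, FALSE),
    mk("quiet", "linear_prior", "female", 0.1, FALSE),
    mk("quiet", "ushape_component", "female", 0.1, FALSE),
    mk("quiet", "ushape_prior", "female", 0.1, FALSE),
    mk("conflict", "linear_component", "female", 0.9, TRUE),
    mk("conflict", "linear_prior", "female", -0.9, TRUE))
  cl <- classify_reaction_norms(res)
  expect_equal(cl$label[cl$metabolite == "proline"], "linear-")
  expect_equal(cl$linear_class[cl$metabolite == "proline"], "-")
  expect_equal(cl$label[cl$metabolite == "nad"], "ushape-")
  expect_equal(cl$label[cl$metabolite == "quiet"], "none")
  expect_equal(cl$label[cl$metabolite == "conflict"], "none")
})
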