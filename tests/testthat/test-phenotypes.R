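noiseless_truth <- function() phenotype_truth(
  ctmin = c(intercept = -4.578, slope = 0.412, sd = 0),
  ctmax = c(intercept = 37.601, slope = 0.123, sex = -0.692,
            sex_by_temp = 0.019, sd = 0),
  viability = c(intercept = 0.8, linear = -0.1, quadratic = -0.5,
                overdispersion = 1),
  devtime = c(intercept = 2.55, linear = -0.67, quadratic = 0.09,
              sex = 0.03, vial_sd = 0))

test_that("noise-free CT_min reduction keeps temperature only, with exact coefficients", {
  sim <- simulate_phenotypes(small_design(), noiseless_truth(), seed = 1)
  fit <- fit_thermal_limit(sim$flies, "ctmin")
  expect_equal(deparse(fit$formula), "value ~ temperature")
  expect_equal(fit$coefficients$estimate,
               c(-4.578, 0.412), tolerance = 1e-10)
  expect_false(fit$reduction$kept[fit$reduction$term == "sex"])
  expect_false(fit$reduction$kept[fit$reduction$term == "sex:temperature"])
})

test_that("a noise-free CT_max interaction is retained and mains are protected", {
  sim <- simulate_phenotypes(small_design(), noiseless_truth(), seed = 1)
  fit <- fit_thermal_limit(sim$flies, "ctmax")
  expect_true(fit$reduction$kept[fit$reduction$term == "sex:temperature"])
  expect_true(all(fit$reduction$kept))
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "temperature"], 0.123,
               tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "sexmale:temperature"], 0.019,
               tolerance = 1e-8)
})

test_that("viability point estimates equal the binomial fit with inflated SEs", {
  sim <- simulate_phenotypes(small_design(vials = 30), phenotype_truth(),
                             seed = 4)
  fit <- fit_viability(sim$vials)
  d <- sim$vials
  d$ts <- (d$temperature - mean(d$temperature)) / stats::sd(d$temperature)
  qfit <- stats::glm(cbind(adults, eggs - adults) ~ ts + I(ts^2),
                     family = stats::quasibinomial(), data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(qfit)),
               tolerance = 1e-10)
  expect_equal(fit$dispersion, summary(qfit)$dispersion, tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(summary(qfit)$coefficients[, 2]) *
                 sqrt(fit$dispersion / summary(qfit)$dispersion),
               tolerance = 1e-6)
  expect_lt(fit$coefficients$estimate[3], 0)
  # the concave fitted curve peaks strictly inside the thermal range
  b <- fit$coefficients$estimate
  ts_max <- -b[2] / (2 * b[3])
  t_max <- ts_max * stats::sd(d$temperature) + mean(d$temperature)
  expect_true(t_max > 12 && t_max < 32)
})

test_that("a zero-variance vial effect reproduces the plain Poisson fit", {
  sim <- simulate_phenotypes(small_design(vials = 12), noiseless_truth(),
                             seed = 2)
  fit <- fit_devtime(sim$flies, reduce = FALSE)
  d <- sim$flies[sim$flies$trait == "devtime", ]
  d$ts <- (d$temperature - mean(d$temperature)) / stats::sd(d$temperature)
  d$sex <- factor(d$sex, levels = c("female", "male"))
  glm_fit <- stats::glm(value ~ ts + I(ts^2) + sex + sex:ts + sex:I(ts^2),
                        family = stats::poisson(), data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(glm_fit)),
               tolerance = 1e-3)
  expect_lt(fit$ranef_sd, 0.05)
})

test_that("devtime reduction drops the null interaction and keeps sex and temperature", {
  d <- small_design(vials = 12)
  sim <- simulate_phenotypes(d, phenotype_truth(
    devtime = c(intercept = 2.55, linear = -0.67, quadratic = 0.09,
                sex = 0.2, vial_sd = 0.03)), seed = 6)
  fit <- fit_devtime(sim$flies)
  red <- fit$reduction
  expect_false(red$kept[red$term == "sex:temperature"])
  expect_true(red$kept[red$term == "sex"])
  expect_true(red$kept[red$term == "temperature (linear + quadratic)"])
  est <- fit$coefficients
  expect_lt(abs(est$estimate[est$term == "sexmale"] - 0.2), 0.05)
})

test_that("refitting the final formula reproduces the reported coefficients", {
  sim <- simulate_phenotypes(small_design(), phenotype_truth(), seed = 14)
  for (trait in c("ctmin", "ctmax")) {
    fit <- fit_thermal_limit(sim$flies, trait)
    d <- sim$flies[sim$flies$trait == trait, ]
    d$sex <- factor(d$sex, levels = c("female", "male"))
    refit <- stats::lm(fit$formula, data = d)
    expect_equal(fit$coefficients$estimate, unname(coef(refit)),
                 tolerance = 1e-10)
  }
})

test_that("the mixed devtime likelihood dominates its fixed-effect submodel", {
  sim <- simulate_phenotypes(small_design(vials = 10), phenotype_truth(),
                             seed = 15)
  fit <- fit_devtime(sim$flies, reduce = FALSE)
  d <- sim$flies[sim$flies$trait == "devtime", ]
  d$ts <- (d$temperature - mean(d$temperature)) / stats::sd(d$temperature)
  d$sex <- factor(d$sex, levels = c("female", "male"))
  glm_fit <- stats::glm(value ~ ts + I(ts^2) + sex + sex:ts + sex:I(ts^2),
                        family = stats::poisson(), data = d)
  expect_gte(as.numeric(stats::logLik(fit$model)),
             as.numeric(stats::logLik(glm_fit)) - 1e-6)
})

test_that("model fitting rejects malformed phenotype records", {
  sim <- simulate_phenotypes(small_design(), phenotype_truth(), seed = 3)
  dv <- sim$flies
  dv$value[dv$trait == "devtime"][1] <- 2.5
  expect_error(fit_devtime(dv), "integer")
  full <- sim$vials
  full$adults <- full$eggs
  expect_error(fit_viability(full), "separation")
  one_sex <- sim$flies[sim$flies$sex == "female", ]
  expect_error(fit_thermal_limit(one_sex, "ctmin"), "both sexes")
})

test_that("condition-level targets cover every spectrum sample or fail loudly", {
  d <- small_design()
  sim <- simulate_phenotypes(d, phenotype_truth(), seed = 8)
  meta <- tidyr::expand_grid(sex = c("female", "male"),
                             temperature = d$temperatures)
  meta$sample_id <- paste0(substr(meta$sex, 1, 1), seq_len(nrow(meta)))
  tg <- phenotype_targets(sim$flies, sim$vials, meta)
  expect_equal(nrow(tg), nrow(meta))
  expect_equal(length(unique(tg$devtime_target)), 6)   # per sex x temp
  expect_equal(length(unique(tg$viability_target)), 3) # per temp, pooled
  # monotone-decreasing planted curve up to 29.5 degC
  dv <- unique(tg[tg$sex == "female", c("temperature", "devtime_target")])
  dv <- dv[order(dv$temperature), ]
  expect_true(all(diff(dv$devtime_target) < 0))
  meta_bad <- dplyr::bind_rows(meta, tibble::tibble(
    sex = "female", temperature = 25, sample_id = "x"))
  expect_error(phenotype_targets(sim$flies, sim$vials, meta_bad),
               "female/25")
})
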