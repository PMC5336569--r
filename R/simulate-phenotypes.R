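#' Ground-truth parameters for the functional phenotypes
#'
#' Defaults follow the study's fitted models: thermal limits linear in
#' developmental temperature (CT_min intercept -4.578, slope 0.412; CT_max
#' 37.601 + 0.123 T with male offset -0.692 and male-by-temperature
#' interaction 0.019 — male coefficients are deviations from females),
#' egg-to-adult viability a concave quadratic on the logit scale over
#' standardized temperature with overdispersion, and developmental time a
#' Poisson log-quadratic with a male offset of 0.03 and a vial random
#' intercept. Viability and developmental-time curvature parameters are
#' chosen to reproduce the reported curve shapes (40-50% viability at the
#' extremes vs 60-80% at intermediate temperatures; ~49 d at 12 degC down
#' to ~7.5 d at 29.5 degC).
#'
#' @param ctmin,ctmax,viability,devtime Named numeric vectors overriding
#'   individual components.
#' @return A `phenotype_truth` list.
#' @export
phenotype_truth <- function(
    ctmin = c(intercept = -4.578, slope = 0.412, sd = 0.5),
    ctmax = c(intercept = 37.601, slope = 0.123, sex = -0.692,
              sex_by_temp = 0.019, sd = 0.5),
    viability = c(intercept = 0.8, linear = -0.1, quadratic = -0.5,
                  overdispersion = 2),
    devtime = c(intercept = 2.55, linear = -0.67, quadratic = 0.09,
                sex = 0.03, vial_sd = 0.05)) {
  if (ctmin[["sd"]] < 0 || ctmax[["sd"]] < 0 || devtime[["vial_sd"]] < 0)
    abort("residual SDs must be >= 0")
  if (viability[["overdispersion"]] < 1)
    abort("overdispersion factor must be >= 1")
  if (viability[["quadratic"]] >= 0)
    abort("viability quadratic coefficient must be < 0 (concave)")
  structure(list(ctmin = ctmin, ctmax = ctmax, viability = viability,
                 devtime = devtime),
            class = "phenotype_truth")
}

#' Simulate individual phenotype records and vial counts
#'
#' Draws CT_min and CT_max for individually assayed flies, overdispersed
#' binomial (beta-binomial) emergence counts per vial, and an integer
#' emergence day for every emerged adult with vial random intercepts on the
#' log scale. Temperatures are standardized internally for the quadratic
#' viability and developmental-time truths. Male coefficients are
#' deviations from females, matching the fitted-model convention.
#'
#' @param design A [simulation_design()].
#' @param truth A [phenotype_truth()].
#' @param seed Integer seed.
#' @return A list with `flies` (tibble: `trait`, `sex`, `temperature`,
#'   `value`, `vial_id`) and `vials` (tibble: `temperature`, `vial_id`,
#'   `eggs`, `adults`).
#' @export
simulate_phenotypes <- function(design, truth = phenotype_truth(), seed) {
  if (length(design$temperatures) < 2)
    abort("quadratic truths need a design with >= 2 temperatures")
  withr_seed(seed)
  temps <- design$temperatures
  ts_mu <- mean(temps)
  ts_sd <- stats::sd(temps)
  std <- function(t) (t - ts_mu) / ts_sd

  # Thermal limits: one record per assayed fly.
  cell <- tidyr::expand_grid(sex = design$sexes, temperature = temps)
  limit_records <- function(trait) {
    tr <- truth[[trait]]
    purrr::pmap_dfr(cell, function(sex, temperature) {
      n <- design$flies_assayed_per_cell
      male <- as.numeric(sex == "male")
      mu <- tr[["intercept"]] + tr[["slope"]] * temperature
      if (trait == "ctmax")
        mu <- mu + male * (tr[["sex"]] + tr[["sex_by_temp"]] * temperature)
      tibble::tibble(trait = trait, sex = sex, temperature = temperature,
                     value = mu + rnorm(n, 0, tr[["sd"]]),
                     vial_id = NA_character_)
    })
  }
  ct <- dplyr::bind_rows(limit_records("ctmin"), limit_records("ctmax"))

  # Vial-level emergence: beta-binomial with variance inflation factor phi.
  vb <- truth$viability
  phi <- vb[["overdispersion"]]
  n_eggs <- design$eggs_per_vial
  vials <- tidyr::expand_grid(temperature = temps,
                              vial = seq_len(design$vials_per_temperature))
  vials$vial_id <- sprintf("T%g_v%d", vials$temperature, vials$vial)
  p_true <- stats::plogis(vb[["intercept"]] + vb[["linear"]] * std(vials$temperature) +
                            vb[["quadratic"]] * std(vials$temperature)^2)
  vials$adults <- if (phi > 1 && n_eggs > 1) {
    rho <- (phi - 1) / (n_eggs - 1)
    a <- p_true * (1 - rho) / rho
    b <- (1 - p_true) * (1 - rho) / rho
    rbinom(nrow(vials), n_eggs, rbeta(nrow(vials), a, b))
  } else {
    rbinom(nrow(vials), n_eggs, p_true)
  }
  vials$eggs <- n_eggs

  # Developmental time: one integer emergence day per emerged adult, with a
  # vial random intercept and random sex assignment.
  dv <- truth$devtime
  u_vial <- rnorm(nrow(vials), 0, dv[["vial_sd"]])
  dev <- purrr::pmap_dfr(
    list(vials$temperature, vials$vial_id, vials$adults, u_vial),
    function(temperature, vial_id, adults, u) {
      if (adults == 0) return(NULL)
      sex <- ifelse(stats::runif(adults) < 0.5, "female", "male")
      male <- as.numeric(sex == "male")
      lmu <- dv[["intercept"]] + dv[["linear"]] * std(temperature) +
        dv[["quadratic"]] * std(temperature)^2 + dv[["sex"]] * male + u
      tibble::tibble(trait = "devtime", sex = sex, temperature = temperature,
                     value = pmax(1, rpois(adults, exp(lmu))),
                     vial_id = vial_id)
    })
  list(flies = dplyr::bind_rows(ct, dev),
       vials = tibble::as_tibble(vials[, c("temperature", "vial_id",
                                           "eggs", "adults")]))
}
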