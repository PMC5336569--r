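# The four functional-phenotype models, fitted with sequential model
# reduction: the interaction is tested first and main effects are never
# dropped while part of a retained interaction.

new_phenofit <- function(trait, family, formula, model, coefficients,
                         reduction, dispersion = NA_real_,
                         ranef_sd = NA_real_, full_coefficients = NULL) {
  structure(list(trait = trait, family = family, formula = formula,
                 model = model, coefficients = coefficients,
                 reduction = reduction, dispersion = dispersion,
                 ranef_sd = ranef_sd,
                 full_coefficients = full_coefficients %||% coefficients),
            class = "phenofit")
}

coef_tibble <- function(fit) {
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                 se = unname(sm[, 2]))
}

#' @export
print.phenofit <- function(x, ...) {
  cat("<phenofit> ", x$trait, " (", x$family, ")\n", sep = "")
  cat("  final model:", deparse(x$formula), "\n")
  print(x$coefficients, n = Inf)
  invisible(x)
}

# F-test p-value comparing nested linear models, with the noiseless
# degenerate cases resolved explicitly: a vanishing extra sum of squares
# is never significant, a non-vanishing one over a zero residual always
# is.
nested_f <- function(reduced, full) {
  a <- stats::anova(reduced, full)
  ss <- a$`Sum of Sq`[2]
  p <- a$`Pr(>F)`[2]
  if (!is.finite(p)) p <- if (abs(ss) < 1e-10) 1 else 0
  list(statistic = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2], p = p)
}

#' Thermal-limit linear model with sequential F-test reduction
#'
#' Fits `trait ~ sex * temperature` by ordinary least squares, drops the
#' interaction when its F-test p-value is at or above `alpha`, then tests
#' each main effect; main effects are never dropped while part of a
#' significant interaction.
#'
#' @param records Fly records tibble with columns `trait`, `sex`,
#'   `temperature`, `value`, containing the requested trait for both sexes
#'   at three or more temperatures.
#' @param trait `"ctmin"` or `"ctmax"`.
#' @param alpha Reduction threshold.
#' @return A `phenofit` with the final coefficients and the full
#'   reduction table.
#' @export
fit_thermal_limit <- function(records, trait = c("ctmin", "ctmax"),
                              alpha = 0.05) {
  trait <- match.arg(trait)
  d <- records[records$trait == trait, ]
  if (length(unique(d$sex)) < 2 || length(unique(d$temperature)) < 3)
    abort("need both sexes and >= 3 temperatures")
  cells <- table(d$sex, d$temperature)
  if (any(cells < 2)) abort("need >= 2 observations per sex x temperature cell")
  d$sex <- factor(d$sex, levels = c("female", "male"))
  full <- stats::lm(value ~ sex * temperature, data = d)
  int <- nested_f(stats::lm(value ~ sex + temperature, data = d), full)
  red <- tibble::tibble(term = "sex:temperature",
                        statistic = int$statistic,
                        df = sprintf("(%d,%d)", int$df1, int$df2),
                        p = int$p, kept = int$p < alpha)
  if (int$p < alpha) {
    final <- full
    red <- dplyr::bind_rows(
      tibble::tibble(term = c("sex", "temperature"), statistic = NA_real_,
                     df = NA_character_, p = NA_real_, kept = TRUE),
      red)
  } else {
    add <- stats::lm(value ~ sex + temperature, data = d)
    sx <- nested_f(stats::lm(value ~ temperature, data = d), add)
    tp <- nested_f(stats::lm(value ~ sex, data = d), add)
    keep <- c(sex = sx$p < alpha, temperature = tp$p < alpha)
    red <- dplyr::bind_rows(
      tibble::tibble(term = "temperature", statistic = tp$statistic,
                     df = sprintf("(%d,%d)", tp$df1, tp$df2),
                     p = tp$p, kept = unname(keep["temperature"])),
      tibble::tibble(term = "sex", statistic = sx$statistic,
                     df = sprintf("(%d,%d)", sx$df1, sx$df2),
                     p = sx$p, kept = unname(keep["sex"])),
      red)
    rhs <- paste(c("sex", "temperature")[keep], collapse = " + ")
    if (rhs == "") rhs <- "1"
    final <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = d)
  }
  new_phenofit(trait, "gaussian", stats::formula(final), final,
               coef_tibble(final), red,
               full_coefficients = coef_tibble(full))
}

#' Quasi-binomial quadratic viability model
#'
#' Logistic regression of per-vial emergence on standardized developmental
#' temperature and its square; overdispersion is estimated as the Pearson
#' chi-square over its residual degrees of freedom and reported standard
#' errors are inflated by its square root. Point estimates equal the
#' plain binomial fit; influential points are retained.
#'
#' @param vials Vial records tibble: `temperature`, `eggs`, `adults`.
#' @return A `phenofit`; `dispersion` holds the estimate, the reduction
#'   table the 2-df likelihood-ratio test of the temperature terms.
#' @export
fit_viability <- function(vials) {
  if (length(unique(vials$temperature)) < 3) abort("need >= 3 temperatures")
  if (all(vials$adults == 0) || all(vials$adults == vials$eggs))
    abort("complete separation: all vials empty or all full")
  d <- vials
  d$ts <- standardize(d$temperature)
  fit <- stats::glm(cbind(adults, eggs - adults) ~ ts + I(ts^2),
                    family = stats::binomial(), data = d)
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  null <- stats::glm(cbind(adults, eggs - adults) ~ 1,
                     family = stats::binomial(), data = d)
  lrt <- stats::anova(null, fit, test = "Chisq")
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                          se = unname(sm[, 2]) * sqrt(disp))
  red <- tibble::tibble(term = "temperature (linear + quadratic)",
                        statistic = lrt$Deviance[2],
                        df = sprintf("(%d)", lrt$Df[2]),
                        p = lrt$`Pr(>Chi)`[2],
                        kept = TRUE)
  new_phenofit("viability", "quasibinomial",
               stats::formula(fit), fit, coefs, red, dispersion = disp)
}

#' Poisson mixed model for developmental time
#'
#' Log-link Poisson GLMM of emergence day on standardized temperature
#' (linear + quadratic), sex, and their interaction, with a vial random
#' intercept, fitted by Laplace-approximated maximum likelihood
#' ([lme4::glmer()]). Fixed effects are reduced by likelihood-ratio
#' tests: the 2-df sex-by-temperature interaction first, then sex, then
#' the temperature terms, halting on a retained interaction.
#'
#' @param records Fly records with `trait == "devtime"`, integer `value`
#'   and `vial_id`; at least two vials.
#' @param alpha Reduction threshold.
#' @param reduce Run the reduction (three extra fits)? When `FALSE`, only
#'   the full additive-plus-interaction model is reported.
#' @return A `phenofit`; `ranef_sd` is the vial random-intercept SD.
#' @export
fit_devtime <- function(records, alpha = 0.05, reduce = TRUE) {
  d <- records[records$trait == "devtime", ]
  if (any(d$value != round(d$value)) || any(d$value < 1))
    abort("developmental time must be positive integers (days)")
  if (length(unique(d$vial_id)) < 2) abort("need >= 2 vials")
  d$ts <- standardize(d$temperature)
  d$sex <- factor(d$sex, levels = c("female", "male"))
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             calc.derivs = FALSE)
  fit_g <- function(fml) suppressMessages(
    lme4::glmer(fml, data = d, family = stats::poisson(), control = ctrl))
  full <- fit_g(value ~ ts + I(ts^2) + sex + sex:ts + sex:I(ts^2) +
                  (1 | vial_id))
  red <- tibble::tibble()
  final <- full
  if (reduce) {
    addm <- fit_g(value ~ ts + I(ts^2) + sex + (1 | vial_id))
    lr_int <- stats::anova(addm, full)
    p_int <- lr_int$`Pr(>Chisq)`[2]
    red <- tibble::tibble(term = "sex:temperature",
                          statistic = lr_int$Chisq[2],
                          df = sprintf("(%d)", lr_int$Df[2]),
                          p = p_int, kept = p_int < alpha)
    if (p_int < alpha) {
      final <- full
      red <- dplyr::bind_rows(
        tibble::tibble(term = c("sex", "temperature"), statistic = NA_real_,
                       df = NA_character_, p = NA_real_, kept = TRUE), red)
    } else {
      nosex <- fit_g(value ~ ts + I(ts^2) + (1 | vial_id))
      notemp <- fit_g(value ~ sex + (1 | vial_id))
      lr_sex <- stats::anova(nosex, addm)
      lr_tmp <- stats::anova(notemp, addm)
      p_sex <- lr_sex$`Pr(>Chisq)`[2]
      p_tmp <- lr_tmp$`Pr(>Chisq)`[2]
      red <- dplyr::bind_rows(
        tibble::tibble(term = "temperature (linear + quadratic)",
                       statistic = lr_tmp$Chisq[2],
                       df = sprintf("(%d)", lr_tmp$Df[2]),
                       p = p_tmp, kept = p_tmp < alpha),
        tibble::tibble(term = "sex", statistic = lr_sex$Chisq[2],
                       df = sprintf("(%d)", lr_sex$Df[2]),
                       p = p_sex, kept = p_sex < alpha),
        red)
      keep <- c(if (p_tmp < alpha) "ts + I(ts^2)", if (p_sex < alpha) "sex")
      rhs <- paste(c(keep, "(1 | vial_id)"), collapse = " + ")
      final <- if (p_tmp < alpha && p_sex < alpha) addm else
        fit_g(stats::as.formula(paste("value ~", rhs)))
    }
  }
  vsd <- sqrt(unname(lme4::VarCorr(final)$vial_id[1]))
  new_phenofit("devtime", "poisson-mixed", stats::formula(final), final,
               coef_tibble(final), red, ranef_sd = vsd,
               full_coefficients = coef_tibble(full))
}

#' Condition-level phenotype targets for OPLS prediction
#'
#' Assigns every spectrum sample the mean observed developmental time of
#' its sex-by-temperature condition and the pooled-sex egg-to-adult
#' viability of its temperature, for use as OPLS response vectors.
#'
#' @param flies Fly records (with `devtime` rows).
#' @param vials Vial records.
#' @param meta Spectrum sample metadata (`sample_id`, `sex`,
#'   `temperature`).
#' @return `meta` with `devtime_target` and `viability_target` columns.
#' @export
phenotype_targets <- function(flies, vials, meta) {
  dv <- flies[flies$trait == "devtime", ] |>
    dplyr::group_by(.data$sex, .data$temperature) |>
    dplyr::summarise(devtime_target = mean(.data$value), .groups = "drop")
  vi <- vials |>
    dplyr::group_by(.data$temperature) |>
    dplyr::summarise(viability_target = sum(.data$adults) / sum(.data$eggs),
                     .groups = "drop")
  out <- meta |>
    dplyr::left_join(dv, by = c("sex", "temperature")) |>
    dplyr::left_join(vi, by = "temperature")
  miss <- out[is.na(out$devtime_target) | is.na(out$viability_target), ]
  if (nrow(miss) > 0)
    abort(paste0("no phenotype data for condition(s): ",
                 paste(unique(sprintf("%s/%g", miss$sex, miss$temperature)),
                       collapse = ", ")))
  out
}
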