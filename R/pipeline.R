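# End-to-end orchestration: simulate -> preprocess -> chemometrics ->
# reaction norms -> phenotypes -> report, under one validated config.

parse_components <- function(a) {
  if (is.numeric(a) && length(a) == 2)
    return(list(pred = as.integer(a[1]), orth = as.integer(a[2])))
  m <- regmatches(a, regexec("^([0-9]+)\\+([0-9]+)$", a))[[1]]
  if (length(m) != 3) abort(paste0("cannot parse component count '", a,
                                   "'; expected the form \"1+2\""))
  list(pred = as.integer(m[2]), orth = as.integer(m[3]))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: the simulation
#' design and truths, preprocessing windows, per-model component counts
#' (in the `"predictive+orthogonal"` string form, e.g. `"1+2"`), the
#' sequential-Bonferroni family settings and the seed. Unknown keys are
#' rejected at construction.
#'
#' @param design A [simulation_design()].
#' @param truths Metabolite truths ([default_metabolite_truths()]).
#' @param phenotypes A [phenotype_truth()].
#' @param nuisance A [nuisance_control()].
#' @param seed Integer seed for every stochastic stage.
#' @param tsp_target,water,keep,max_shift,bin_width Preprocessing windows
#'   (ppm). The default keep-window upper edge is 9.6 so the highest
#'   assigned signal (nicotinamide ribotide, integrated at 9.581-9.595
#'   ppm) survives trimming.
#' @param components Named list of `"1+n"` component strings for the four
#'   OPLS targets (`linear`, `ushape`, `devtime`, `viability`).
#' @param oplsda List with `n_pred` and `n_orth` (an integer, or `"cv"`
#'   to select 0-3 by cross-validated accuracy).
#' @param pca_k Components retained in the per-sex PCA.
#' @param assumed_m,alpha Sequential-Bonferroni family size and level.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = default_design(),
                            truths = default_metabolite_truths(),
                            phenotypes = phenotype_truth(),
                            nuisance = nuisance_control(),
                            seed = 1L,
                            tsp_target = -0.017,
                            water = c(4.67, 4.85),
                            keep = c(0.5, 9.6),
                            max_shift = 0.01,
                            bin_width = NULL,
                            components = list(linear = "1+2", ushape = "1+1",
                                              devtime = "1+2",
                                              viability = "1+2"),
                            oplsda = list(n_pred = 3, n_orth = "cv"),
                            pca_k = 5,
                            assumed_m = 100,
                            alpha = 0.05) {
  cfg <- list(design = design, truths = truths, phenotypes = phenotypes,
              nuisance = nuisance, seed = seed, tsp_target = tsp_target,
              water = water, keep = keep, max_shift = max_shift,
              bin_width = bin_width, components = components,
              oplsda = oplsda, pca_k = pca_k, assumed_m = assumed_m,
              alpha = alpha)
  lapply(cfg$components, parse_components)  # fail fast on bad "1+n" strings
  if (cfg$assumed_m < nrow(cfg$truths))
    abort(sprintf(
      "assumed_m = %d is below the %d metabolites tested", cfg$assumed_m,
      nrow(cfg$truths)))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys override [pipeline_config()] defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0)
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  if (!is.null(y$design)) y$design <- do.call(simulation_design, y$design)
  if (!is.null(y$nuisance)) y$nuisance <- do.call(nuisance_control, y$nuisance)
  if (!is.null(y$phenotypes))
    y$phenotypes <- do.call(phenotype_truth, lapply(y$phenotypes, unlist))
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  object_md5(lapply(unclass(config), function(x)
    if (is.function(x)) deparse(x) else x))
}

fm_subset <- function(fm, idx) {
  new_feature_matrix(fm$values[idx, , drop = FALSE], fm$ppm,
                     fm$meta[idx, ], normalized = fm$normalized,
                     scaling = fm$scaling, log = fm$log)
}

condition_code <- function(sex, temperature)
  sprintf("%s%g", toupper(substr(sex, 1, 1)), temperature)

# One OPLS target: full fit on the Pareto-scaled matrix (R2X/R2Y, scores
# oriented to correlate positively with y) plus leave-condition-out Q2 on
# the unscaled matrix.
opls_target <- function(fm_raw, fm_scaled, y, groups, comps) {
  fit <- fit_opls(fm_scaled, y, n_orth = comps$orth)
  if (stats::cor(fit$scores, y) < 0) fit$scores <- -fit$scores
  fit$Q2 <- grouped_q2(fm_raw, y, groups, n_orth = comps$orth)
  fit
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — simulation, preprocessing (TSP
#' referencing, alignment, trimming, total-intensity normalization),
#' per-sex PCA with rotation into linear and U-shape components, OPLS
#' models with leave-condition-out Q2 for the linear prior, U-shape
#' prior, developmental time (per sex) and pooled viability, OPLS-DA over
#' the sex-by-temperature conditions with Ward clustering, metabolite
#' integration, correlation screening with sequential Bonferroni
#' correction and reaction-norm classification against the planted truth,
#' the sex-difference analysis, and the four phenotype models — and
#' returns a report bundle stamped with the config hash and seed.
#'
#' @param config A [pipeline_config()].
#' @param cache_dir Optional directory for stage caching: the simulation
#'   and preprocessing stages are stored keyed by the config hash and
#'   reused on re-runs.
#' @param quiet Suppress per-stage progress messages?
#' @return A `report_bundle` list (see Details in the package vignette).
#' @export
run_pipeline <- function(config = pipeline_config(), cache_dir = NULL,
                         quiet = TRUE) {
  if (!inherits(config, "pipeline_config"))
    abort("`config` must be a pipeline_config")
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e))))
    say("stage %-12s %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  cached_stage <- function(name, expr) {
    if (is.null(cache_dir)) return(stage(name, expr))
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(cache_dir, paste0(hash, "_", name, ".rds"))
    if (file.exists(f)) return(readRDS(f))
    out <- stage(name, expr)
    saveRDS(out, f)
    out
  }

  sim <- cached_stage("simulate", {
    list(spectra = simulate_spectra(config$design, config$truths,
                                    config$nuisance, seed = config$seed),
         phen = simulate_phenotypes(config$design, config$phenotypes,
                                    seed = config$seed + 1L))
  })

  set <- cached_stage("preprocess", {
    sim$spectra |>
      reference_set(tsp_target = config$tsp_target) |>
      align_set(max_shift = config$max_shift) |>
      trim_set(water = config$water, keep = config$keep) |>
      normalize_total()
  })
  fm <- to_feature_matrix(set, bin_width = config$bin_width)
  meta <- fm$meta
  targets_tbl <- phenotype_targets(sim$phen$flies, sim$phen$vials, meta)

  chem <- stage("chemometrics", {
    per_sex <- lapply(stats::setNames(nm = config$design$sexes), function(sx) {
      idx <- which(meta$sex == sx)
      sub_raw <- fm_subset(fm, idx)
      sub_scaled <- pareto_scale(sub_raw, centered = TRUE)
      p <- fit_pca(sub_scaled, k = config$pca_k, centered = TRUE)
      rot <- rotate_to_target(p, sub_raw$meta$temperature)
      # orient: linear component rises with temperature, U-shape component
      # rises with the extreme encoding
      if (stats::cor(rot$linear_scores, sub_raw$meta$temperature) < 0) {
        rot$linear_scores <- -rot$linear_scores
        rot$linear_loadings <- -rot$linear_loadings
        rot$r_linear <- -rot$r_linear
      }
      ench <- ushape_prior_encoding(sub_raw$meta$temperature)
      if (stats::cor(rot$ushape_scores, ench) < 0) {
        rot$ushape_scores <- -rot$ushape_scores
        rot$ushape_loadings <- -rot$ushape_loadings
      }
      grp <- condition_code(sub_raw$meta$sex, sub_raw$meta$temperature)
      tt <- targets_tbl[idx, ]
      list(idx = idx, raw = sub_raw, scaled = sub_scaled, pca = p, rot = rot,
           opls_linear = opls_target(
             sub_raw, sub_scaled, sub_raw$meta$temperature, grp,
             parse_components(config$components$linear)),
           opls_ushape = opls_target(
             sub_raw, sub_scaled, ench, grp,
             parse_components(config$components$ushape)),
           opls_devtime = opls_target(
             sub_raw, sub_scaled, tt$devtime_target, grp,
             parse_components(config$components$devtime)))
    })
    fm_scaled <- pareto_scale(fm, centered = TRUE)
    grp_all <- condition_code(meta$sex, meta$temperature)
    opls_via <- opls_target(fm, fm_scaled, targets_tbl$viability_target,
                            grp_all,
                            parse_components(config$components$viability))
    list(per_sex = per_sex, fm_scaled = fm_scaled, opls_viability = opls_via)
  })

  table3 <- {
    row3 <- function(param, who, fit)
      tibble::tibble(predicted_parameter = param, metabolome = who,
                     A = fit$A, N = fit$N, R2 = fit$R2X, Q2 = fit$Q2)
    dplyr::bind_rows(
      row3("Linear prior", "Male", chem$per_sex$male$opls_linear),
      row3("Linear prior", "Female", chem$per_sex$female$opls_linear),
      row3("U-shape prior", "Male", chem$per_sex$male$opls_ushape),
      row3("U-shape prior", "Female", chem$per_sex$female$opls_ushape),
      row3("Developmental time", "Male", chem$per_sex$male$opls_devtime),
      row3("Developmental time", "Female", chem$per_sex$female$opls_devtime),
      row3("Egg-to-adult viability", "Both", chem$opls_viability))
  }

  clust <- stage("oplsda_hca", {
    classes <- condition_code(meta$sex, meta$temperature)
    n_orth <- config$oplsda$n_orth
    if (identical(n_orth, "cv"))
      n_orth <- select_oplsda_n_orth(fm$values, classes,
                                     n_pred = config$oplsda$n_pred,
                                     seed = config$seed)
    da <- fit_oplsda(chem$fm_scaled, classes,
                     n_pred = config$oplsda$n_pred, n_orth = n_orth)
    cm <- rowsum(da$scores, classes) / as.vector(table(classes))
    dend <- hca_ward(cm, labels = rownames(cm))
    list(model = da, condition_means = cm, dendrogram = dend,
         newick = as_newick(dend))
  })

  sexdiff <- stage("sexdiff", {
    dm <- sex_difference_matrix(set)
    list(matrix = dm, analysis = sex_difference_analysis(dm))
  })

  norms <- stage("reaction_norms", {
    intens <- integrate_metabolites(set, config$truths)
    res <- list()
    for (sx in config$design$sexes) {
      ps <- chem$per_sex[[sx]]
      sub_set <- set
      sub_set$intensities <- set$intensities[ps$idx, , drop = FALSE]
      sub_set$meta <- set$meta[ps$idx, ]
      tab <- intens[ps$idx, ]
      tgts <- list(linear_component = ps$rot$linear_scores,
                   ushape_component = ps$rot$ushape_scores,
                   linear_prior = ps$opls_linear$scores,
                   ushape_prior = ps$opls_ushape$scores,
                   devtime = ps$opls_devtime$scores)
      for (nm in names(tgts))
        res[[paste(sx, nm)]] <- correlate_with_target(
          tab, tgts[[nm]], config$truths, sub_set,
          target = nm, sex_context = sx)
    }
    res[["both viability"]] <- correlate_with_target(
      intens, chem$opls_viability$scores, config$truths, set,
      target = "viability", sex_context = "both")
    dm <- sexdiff$matrix
    res[["both sexdiff"]] <- correlate_with_target(
      integrate_metabolites(dm, config$truths),
      sexdiff$analysis$scores$PC1, config$truths, dm,
      target = "sexdiff", sex_context = "both")
    all_res <- holm_significance(dplyr::bind_rows(res),
                                 assumed_m = config$assumed_m,
                                 alpha = config$alpha)
    classes <- classify_reaction_norms(all_res)
    truth <- truth_table(config$truths)
    confusion <- classes |>
      dplyr::left_join(truth, by = c(metabolite = "name")) |>
      dplyr::mutate(
        expected_linear_class = ifelse(.data$expected_linear == "0", "none",
                                       .data$expected_linear),
        expected_ushape_class = ifelse(.data$expected_ushape == "0", "none",
                                       .data$expected_ushape),
        linear_correct = .data$linear_class == .data$expected_linear_class,
        ushape_correct = .data$ushape_class == .data$expected_ushape_class)
    planted <- confusion[confusion$norm_class %in%
                           c("linear_up", "linear_down",
                             "ushape_up", "ushape_down"), ]
    lin_rows <- startsWith(planted$norm_class, "linear")
    recovery <- mean(c(planted$linear_correct[lin_rows],
                       planted$ushape_correct[!lin_rows]))
    nulls <- confusion[confusion$norm_class == "null", ]
    list(correlations = all_res, classification = classes,
         confusion = confusion, recovery = recovery,
         null_flagged = any(nulls$label != "none"))
  })

  phen_fits <- stage("phenotypes", {
    list(ctmin = fit_thermal_limit(sim$phen$flies, "ctmin",
                                   alpha = config$alpha),
         ctmax = fit_thermal_limit(sim$phen$flies, "ctmax",
                                   alpha = config$alpha),
         viability = fit_viability(sim$phen$vials),
         devtime = fit_devtime(sim$phen$flies, alpha = config$alpha))
  })

  bundle <- structure(list(
    config = config, config_hash = hash, seed = config$seed,
    table3 = table3,
    correlations = norms$correlations,
    classification = norms$classification,
    confusion = norms$confusion,
    recovery = norms$recovery,
    null_flagged = norms$null_flagged,
    newick = clust$newick,
    condition_means = clust$condition_means,
    oplsda_A = clust$model$A,
    sexdiff_fits = sexdiff$analysis$cubic_fits,
    sexdiff_score_length = sexdiff$analysis$score_length,
    phenotypes = lapply(phen_fits, function(f)
      list(trait = f$trait, family = f$family,
           formula = deparse(f$formula), coefficients = f$coefficients,
           full_coefficients = f$full_coefficients,
           reduction = f$reduction, dispersion = f$dispersion,
           ranef_sd = f$ranef_sd)),
    targets = targets_tbl),
    class = "report_bundle")
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> seed ", x$seed, ", config ", substr(x$config_hash, 1, 8),
      "\n", sep = "")
  cat("  OPLS prediction (Table-3 layout):\n")
  print(as.data.frame(x$table3), row.names = FALSE, digits = 3)
  cat(sprintf("  reaction-norm recovery: %.0f%%; null metabolite flagged: %s\n",
              100 * x$recovery, x$null_flagged))
  invisible(x)
}

#' Render a report bundle to files
#'
#' Writes the Table-3-shaped OPLS statistics, the long-format correlation
#' table, the classification and truth-confusion tables, the dendrogram
#' (Newick), the sex-difference fits, JSON phenotype-model summaries with
#' a text rendering, and a human-readable summary of significant
#' metabolites per reaction-norm class and sex.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
render_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_csv(bundle$table3, p("opls_models.csv"))
  readr::write_csv(bundle$correlations, p("correlations.csv"))
  readr::write_csv(bundle$classification, p("classification.csv"))
  readr::write_csv(bundle$confusion, p("confusion.csv"))
  readr::write_csv(bundle$sexdiff_score_length, p("sexdiff_score_length.csv"))
  writeLines(bundle$newick, p("dendrogram.nwk"))
  jsonlite::write_json(
    list(config_hash = bundle$config_hash, seed = bundle$seed,
         phenotypes = lapply(bundle$phenotypes, function(f)
           f[c("trait", "family", "formula", "dispersion", "ranef_sd")])),
    p("phenotypes.json"), auto_unbox = TRUE, digits = NA, na = "null")
  txt <- c("Phenotype models (term, estimate, SE, statistic(df), p)", "")
  for (f in bundle$phenotypes) {
    txt <- c(txt, paste0("== ", f$trait, " [", f$family, "] ",
                         f$formula))
    co <- f$coefficients
    txt <- c(txt, sprintf("  %-28s %9.3f %8.3f", co$term, co$estimate, co$se))
    rd <- f$reduction
    if (nrow(rd) > 0)
      txt <- c(txt, sprintf("  test %-24s %8.2f %-8s p=%-8.3g %s",
                            rd$term, rd$statistic, rd$df, rd$p,
                            ifelse(rd$kept, "kept", "dropped")))
    txt <- c(txt, "")
  }
  writeLines(txt, p("phenotypes.txt"))
  sig <- bundle$classification[bundle$classification$label != "none", ]
  sum_txt <- c(sprintf("config %s  seed %d", bundle$config_hash, bundle$seed),
               sprintf("reaction-norm recovery: %.0f%%", 100 * bundle$recovery),
               "")
  sum_txt <- c(sum_txt, if (nrow(sig) == 0)
    "No metabolite reached significance." else
      sprintf("%-22s %-8s %s", sig$metabolite, sig$sex_context, sig$label))
  writeLines(sum_txt, p("summary.txt"))
  jsonlite::write_json(list(config_hash = bundle$config_hash,
                            seed = bundle$seed),
                       p("provenance.json"), auto_unbox = TRUE)
  invisible(vapply(c("opls_models.csv", "correlations.csv",
                     "classification.csv", "confusion.csv",
                     "sexdiff_score_length.csv", "dendrogram.nwk",
                     "phenotypes.json", "phenotypes.txt", "summary.txt",
                     "provenance.json"), p, character(1)))
}

#' Hash of a report bundle
#'
#' Two runs with the same config and seed hash identically.
#'
#' @param bundle A `report_bundle`.
#' @return md5 string.
#' @export
bundle_hash <- function(bundle) object_md5(unclass(bundle)[
  setdiff(names(bundle), "config")])
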