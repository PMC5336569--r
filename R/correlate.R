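#' Correlate metabolite intensities with a target score vector
#'
#' Pearson correlation of each metabolite's integrated intensity with a
#' per-sample target (a rotated component, an OPLS score vector, or a
#' phenotype-derived score), with a two-sided p-value. Each correlation is
#' additionally verified at the metabolite's other characteristic shifts:
#' the intensity in a +/- 0.005 ppm window around every other listed shift
#' is correlated with the same target, and `verified` is `TRUE` when all
#' windows that are themselves nominally significant (p < 0.05) agree in
#' sign with the primary correlation.
#'
#' @param table Metabolite intensity tibble from
#'   [integrate_metabolites()]; rows must match `target_scores`.
#' @param target_scores Per-sample numeric target.
#' @param defs Metabolite definitions.
#' @param x The `spectrum_set` or `feature_matrix` the table was
#'   integrated from (for the verification windows).
#' @param target Label stored in the `target` column.
#' @param sex_context `"female"`, `"male"` or `"both"`.
#' @return Tibble of correlation results: `metabolite`, `target`,
#'   `sex_context`, `r`, `p`, `n`, `tested`, `verified`.
#' @export
correlate_with_target <- function(table, target_scores, defs, x,
                                  target = "target",
                                  sex_context = "both") {
  mets <- intersect(defs$name, names(table))
  if (length(mets) == 0) abort("no metabolite columns found in `table`")
  if (nrow(table) != length(target_scores))
    abort("`target_scores` must have one value per table row")
  res <- purrr::map_dfr(mets, function(m) {
    v <- table[[m]]
    if (stats::sd(v) == 0 || !all(is.finite(v))) {
      warn(paste0("zero-variance intensity for '", m, "'; excluded"))
      return(tibble::tibble(metabolite = m, target = target,
                            sex_context = sex_context, r = NA_real_,
                            p = NA_real_, n = length(v), tested = FALSE,
                            verified = NA))
    }
    ct <- stats::cor.test(v, target_scores)
    r <- unname(ct$estimate)
    shifts <- defs$shifts[[match(m, defs$name)]]
    lo <- defs$range_low[match(m, defs$name)]
    hi <- defs$range_high[match(m, defs$name)]
    others <- shifts[shifts < lo - 0.005 | shifts > hi + 0.005]
    verified <- TRUE
    for (sh in others) {
      w <- shift_window_intensity(x, sh)
      if (is.null(w) || stats::sd(w) == 0) next
      wt <- stats::cor.test(w, target_scores)
      if (wt$p.value < 0.05 && sign(unname(wt$estimate)) != sign(r))
        verified <- FALSE
    }
    tibble::tibble(metabolite = m, target = target,
                   sex_context = sex_context, r = r, p = ct$p.value,
                   n = length(v), tested = TRUE, verified = verified)
  })
  res
}

# Step-down (Holm) flags for one vector of p-values with denominators
# starting at the assumed family size m: the i-th smallest p is
# significant iff p_(j) <= alpha / (m - j + 1) for every j <= i.
holm_flags <- function(p, assumed_m, alpha) {
  k <- length(p)
  if (assumed_m < k) abort("assumed_m must be >= the number of tested p-values")
  ord <- order(p)
  thr <- alpha / (assumed_m - seq_len(k) + 1)
  ok <- cumprod(p[ord] <= thr) > 0
  out <- logical(k)
  out[ord] <- ok
  out
}

#' Sequential Bonferroni (Holm) significance over correlation results
#'
#' Applies the step-down procedure separately within each target-by-sex
#' family, with denominators starting at an assumed total number of
#' metabolites (100 in the study) rather than the number actually tested —
#' so the strictest threshold is `alpha / assumed_m`.
#'
#' @param results Correlation results from [correlate_with_target()]
#'   (possibly several targets and sex contexts bound together).
#' @param assumed_m Assumed family size; must be at least the number of
#'   tested p-values in every family.
#' @param alpha Family-wise error rate.
#' @return `results` with a logical `significant` column (`FALSE` for
#'   untested rows).
#' @export
holm_significance <- function(results, assumed_m = 100, alpha = 0.05) {
  results |>
    dplyr::group_by(.data$target, .data$sex_context) |>
    dplyr::group_modify(function(g, key) {
      g$significant <- FALSE
      idx <- which(g$tested & !is.na(g$p))
      if (length(idx) > 0)
        g$significant[idx] <- holm_flags(g$p[idx], assumed_m, alpha)
      g
    }) |>
    dplyr::ungroup()
}

# Consensus signed label over the significant results of one shape family
# (component + prior targets): "+"/"-" when all significant correlations
# agree in sign, "none" otherwise.
shape_label <- function(rs) {
  sig <- rs[rs$significant %in% TRUE, , drop = FALSE]
  if (nrow(sig) == 0) return("none")
  s <- unique(sign(sig$r))
  if (length(s) != 1) return("none")
  if (s > 0) "+" else "-"
}

#' Classify per-metabolite reaction norms
#'
#' Combines Holm-flagged correlation results on the four temperature
#' targets (`linear_component`, `linear_prior`, `ushape_component`,
#' `ushape_prior`) into a per-metabolite, per-sex label. A shape label
#' requires significance on the rotated-component target or the prior
#' target for that shape; a negative U-shape label is the inverted-U
#' (bell-shaped) norm. A metabolite may carry both a linear and a U-shape
#' label.
#'
#' @param results Output of [holm_significance()].
#' @return Tibble: `metabolite`, `sex_context`, `linear_class`,
#'   `ushape_class` (each `"+"`, `"-"` or `"none"`) and a combined
#'   `label`.
#' @export
classify_reaction_norms <- function(results) {
  if (!"significant" %in% names(results))
    abort("run holm_significance() first")
  results |>
    dplyr::filter(.data$target %in% c("linear_component", "linear_prior",
                                      "ushape_component", "ushape_prior")) |>
    dplyr::group_by(.data$metabolite, .data$sex_context) |>
    dplyr::group_modify(function(g, key) {
      lin <- shape_label(g[startsWith(g$target, "linear"), ])
      ush <- shape_label(g[startsWith(g$target, "ushape"), ])
      lab <- c(if (lin != "none") paste0("linear", lin),
               if (ush != "none") paste0("ushape", ush))
      tibble::tibble(linear_class = lin, ushape_class = ush,
                     label = if (length(lab)) paste(lab, collapse = "/")
                     else "none")
    }) |>
    dplyr::ungroup()
}
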