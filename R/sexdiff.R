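#' Spectral sex-difference matrix
#'
#' For each temperature, forms the difference between every individual
#' female spectrum and the pointwise median male spectrum (rows tagged
#' `F-medM`) and between the pointwise median female spectrum and every
#' individual male spectrum (rows tagged `medF-M`). With the default
#' design this yields 10 rows per temperature. The result is an
#' uncentered difference feature matrix; deviation from zero carries the
#' sex signal.
#'
#' @param set A normalized `spectrum_set` with both sexes at every
#'   temperature.
#' @return A `feature_matrix` of difference rows with metadata columns
#'   `sample_id`, `tagging`, `temperature`, `source_id`.
#' @export
sex_difference_matrix <- function(set) {
  if (!step_applied(set, "normalize"))
    abort("sex differences are computed on normalized spectra")
  meta <- set$meta
  temps <- sort(unique(meta$temperature))
  rows <- list(); info <- list()
  for (tt in temps) {
    f <- which(meta$temperature == tt & meta$sex == "female")
    m <- which(meta$temperature == tt & meta$sex == "male")
    if (length(f) == 0 || length(m) == 0)
      abort(sprintf("temperature %g is missing one sex", tt))
    med_m <- apply(set$intensities[m, , drop = FALSE], 2, stats::median)
    med_f <- apply(set$intensities[f, , drop = FALSE], 2, stats::median)
    for (i in f) {
      rows[[length(rows) + 1L]] <- set$intensities[i, ] - med_m
      info[[length(info) + 1L]] <-
        tibble::tibble(tagging = "F-medM", temperature = tt,
                       source_id = meta$sample_id[i])
    }
    for (i in m) {
      rows[[length(rows) + 1L]] <- med_f - set$intensities[i, ]
      info[[length(info) + 1L]] <-
        tibble::tibble(tagging = "medF-M", temperature = tt,
                       source_id = meta$sample_id[i])
    }
  }
  meta_out <- dplyr::bind_rows(info)
  meta_out$sample_id <- sprintf("d%03d_%s", seq_len(nrow(meta_out)),
                                meta_out$source_id)
  meta_out <- meta_out[, c("sample_id", "tagging", "temperature", "source_id")]
  new_feature_matrix(do.call(rbind, rows), set$ppm, meta_out,
                     normalized = TRUE, scaling = "none",
                     log = c(set$log, "sex_difference"))
}

#' Uncentered PCA of the sex-difference matrix and its temperature trend
#'
#' Pareto-scales the difference matrix without centering (so score
#' magnitude measures sex differentiation), runs an uncentered PCA,
#' orients PC1 so its grand mean is non-negative, fits PC1 against
#' developmental temperature with linear, quadratic and cubic terms
#' separately for the two row taggings, and reports the total score
#' length per temperature (root of the summed squared per-component mean
#' scores).
#'
#' @param diff A `feature_matrix` from [sex_difference_matrix()]; scaled
#'   internally with uncentered Pareto scaling if still unscaled.
#' @param k Number of components retained (capped at the achievable rank).
#' @return A `sexdiff_result`: `scores` tibble (metadata + PC columns),
#'   `cubic_fits` tibble (per tagging: coefficients, F, df, p),
#'   `score_length` tibble (per temperature) and `k`.
#' @export
sex_difference_analysis <- function(diff, k = 10) {
  if (!inherits(diff, "feature_matrix"))
    abort("`diff` must be a feature_matrix")
  if (diff$scaling == "none") {
    if (all(diff$values == 0)) {
      warn("all-zero difference matrix; returning zero scores")
      scores <- matrix(0, nrow(diff$values), 1)
      sc <- dplyr::bind_cols(diff$meta, tibble::tibble(PC1 = scores[, 1]))
      sl <- sc |>
        dplyr::group_by(.data$temperature) |>
        dplyr::summarise(score_length = 0, .groups = "drop")
      return(structure(list(scores = sc, cubic_fits = tibble::tibble(),
                            score_length = sl, k = 1L),
                       class = "sexdiff_result"))
    }
    diff <- suppressWarnings(pareto_scale(diff, centered = FALSE))
  }
  k <- min(k, nrow(diff$values) - 1L, ncol(diff$values))
  p <- fit_pca(diff, k = min(k, qr(diff$values)$rank), centered = FALSE)
  scores <- p$scores
  if (mean(scores[, 1]) < 0) scores[, 1] <- -scores[, 1]
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  sc <- dplyr::bind_cols(diff$meta, tibble::as_tibble(scores))
  fits <- sc |>
    dplyr::group_by(.data$tagging) |>
    dplyr::group_modify(function(g, key) {
      fit <- stats::lm(PC1 ~ temperature + I(temperature^2) +
                         I(temperature^3), data = g)
      fs <- summary(fit)$fstatistic
      tibble::tibble(
        F = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
        p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
        coefficients = list(stats::coef(fit)))
    }) |>
    dplyr::ungroup()
  sl <- sc |>
    dplyr::group_by(.data$temperature) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("PC"), mean),
                     .groups = "drop")
  pc_cols <- grep("^PC", names(sl))
  sl$score_length <- sqrt(rowSums(as.matrix(sl[, pc_cols])^2))
  structure(list(scores = sc, cubic_fits = fits,
                 score_length = sl[, c("temperature", "score_length")],
                 k = ncol(scores)),
            class = "sexdiff_result")
}

#' @export
print.sexdiff_result <- function(x, ...) {
  cat("<sexdiff_result> ", nrow(x$scores), " difference rows, ",
      x$k, " components\n", sep = "")
  if (nrow(x$cubic_fits) > 0)
    for (i in seq_len(nrow(x$cubic_fits)))
      cat(sprintf("  %s: F(%d,%d) = %.2f, p = %.3g\n",
                  x$cubic_fits$tagging[i], x$cubic_fits$df1[i],
                  x$cubic_fits$df2[i], x$cubic_fits$F[i], x$cubic_fits$p[i]))
  invisible(x)
}
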