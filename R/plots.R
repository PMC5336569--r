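# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_col labs facet_wrap scale_fill_gradient2 theme_minimal
#' @export
ggplot2::autoplot

#' Score plot of a PCA model
#'
#' @param object A `pca_model` whose metadata carries `temperature` and
#'   `sex`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_model <- function(object, ...) {
  d <- tidy(object)
  ev <- object$explained_variance_fraction
  ggplot(d, aes(x = .data$PC1, y = .data$PC2,
                colour = .data$temperature,
                shape = .data$sex)) +
    geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.0f%%)", 100 * ev[1]),
         y = sprintf("PC2 (%.0f%%)", 100 * ev[2]),
         colour = "temperature (°C)") +
    theme_minimal()
}

#' Rotated component scores against developmental temperature
#'
#' @param object A `rotated_components`.
#' @param ... Unused.
#' @return A ggplot with the linear and U-shape reaction norms of the
#'   overall metabolome.
#' @export
autoplot.rotated_components <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("linear", "ushape"), names_to = "component",
                        values_to = "score")
  ggplot(d, aes(x = .data$temperature, y = .data$score)) +
    geom_point(alpha = 0.6) +
    facet_wrap(~component, scales = "free_y") +
    labs(x = "developmental temperature (°C)", y = "rotated score") +
    theme_minimal()
}

#' Observed vs cross-validated structure of an OPLS model
#'
#' @param object An `opls_model`.
#' @param ... Unused.
#' @return A ggplot of fitted against observed response.
#' @export
autoplot.opls_model <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$y, y = .data$fitted)) +
    geom_point() +
    geom_line(aes(y = .data$y), linetype = 2) +
    labs(x = "observed response", y = "fitted response",
         subtitle = sprintf("A = %s, R2Y = %.2f%s", object$A, object$R2Y,
                            if (is.na(object$Q2)) "" else
                              sprintf(", Q2 = %.2f", object$Q2))) +
    theme_minimal()
}

#' Heatmap of significant metabolite correlations
#'
#' Correlation coefficients of each metabolite with each target, shown
#' only where the sequential-Bonferroni flag is set (the layout of the
#' study's correlation figure).
#'
#' @param results Output of [holm_significance()].
#' @return A ggplot.
#' @export
plot_correlation_map <- function(results) {
  d <- results |>
    dplyr::filter(.data$tested) |>
    dplyr::mutate(shown = ifelse(.data$significant, .data$r, NA_real_),
                  column = paste(.data$target, .data$sex_context))
  ggplot(d, aes(x = .data$column, y = .data$metabolite,
                fill = .data$shown)) +
    geom_tile(colour = "grey85") +
    scale_fill_gradient2(limits = c(-1, 1), na.value = "white",
                         name = "r (significant)") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sex differentiation across temperatures
#'
#' Mean PC1 of the sex-difference PCA and the total score length per
#' developmental temperature.
#'
#' @param x A `sexdiff_result`.
#' @return A ggplot.
#' @export
plot_sexdiff <- function(x) {
  means <- x$scores |>
    dplyr::group_by(.data$temperature) |>
    dplyr::summarise(PC1 = mean(.data$PC1), .groups = "drop")
  d <- dplyr::left_join(means, x$score_length, by = "temperature") |>
    tidyr::pivot_longer(c("PC1", "score_length"))
  ggplot(d, aes(x = .data$temperature, y = .data$value)) +
    geom_point() + geom_line() +
    facet_wrap(~name, scales = "free_y") +
    labs(x = "developmental temperature (°C)", y = "score") +
    theme_minimal()
}
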