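# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PCA model
#'
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return Tibble of sample metadata plus one `PC<i>` score column per
#'   component.
#' @export
tidy.pca_model <- function(x, ...) {
  sc <- x$scores
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  dplyr::bind_cols(x$meta, tibble::as_tibble(sc))
}

#' @rdname tidy.pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(n_components = ncol(x$scores),
                 n_samples = nrow(x$scores),
                 explained_variance = sum(x$explained_variance_fraction),
                 centered = x$centered, scaling = x$scaling)
}

#' Tidy rotated components
#'
#' @param x A `rotated_components`.
#' @param ... Unused.
#' @return Tibble of sample metadata plus `linear` and `ushape` scores.
#' @export
tidy.rotated_components <- function(x, ...) {
  dplyr::bind_cols(x$meta,
                   tibble::tibble(linear = x$linear_scores,
                                  ushape = x$ushape_scores))
}

#' @rdname tidy.rotated_components
#' @export
glance.rotated_components <- function(x, ...) {
  tibble::tibble(angle_deg = x$angle * 180 / pi, r_linear = x$r_linear)
}

#' Tidy an OPLS model
#'
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return Tibble with predictive and orthogonal scores, observed and
#'   fitted responses.
#' @export
tidy.opls_model <- function(x, ...) {
  out <- tibble::tibble(t_pred = x$scores, y = x$y, fitted = x$fitted)
  for (j in seq_along(x$orth_scores))
    out[[paste0("t_orth", j)]] <- x$orth_scores[[j]]
  out
}

#' @rdname tidy.opls_model
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(A = x$A, N = x$N, R2X = x$R2X, R2Y = x$R2Y, Q2 = x$Q2)
}

#' Tidy a fitted phenotype model
#'
#' @param x A `phenofit`.
#' @param ... Unused.
#' @return Coefficient tibble (`term`, `estimate`, `se`); SEs are the
#'   dispersion-corrected ones for the quasi-binomial viability model.
#' @export
tidy.phenofit <- function(x, ...) x$coefficients

#' @rdname tidy.phenofit
#' @export
glance.phenofit <- function(x, ...) {
  tibble::tibble(trait = x$trait, family = x$family,
                 formula = deparse(x$formula), dispersion = x$dispersion,
                 ranef_sd = x$ranef_sd)
}
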