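#' Principal component analysis of a feature matrix
#'
#' Thin SVD of the (optionally column-centered) matrix. Scores are
#' `U d`, loadings the right singular vectors; component signs follow the
#' convention that each loading's largest-magnitude element is positive.
#'
#' @param m A `feature_matrix` (or plain matrix).
#' @param k Number of components; must not exceed the achievable rank.
#' @param centered Column-center before decomposition? Uncentered PCA is
#'   used for the sex-difference analysis, where deviation from zero is
#'   the signal.
#' @return A `pca_model` with `scores`, `loadings`,
#'   `explained_variance_fraction`, `center`, `scaling` and `meta`.
#' @export
fit_pca <- function(m, k = 2, centered = TRUE) {
  x <- if (inherits(m, "feature_matrix")) m$values else as.matrix(m)
  meta <- if (inherits(m, "feature_matrix")) m$meta else
    tibble::tibble(sample_id = rownames(x) %||% as.character(seq_len(nrow(x))))
  scaling <- if (inherits(m, "feature_matrix")) m$scaling else "none"
  center <- if (centered) colMeans(x) else NULL
  xc <- if (centered) sweep(x, 2, center) else x
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (k > rank)
    abort(sprintf("k = %d exceeds the achievable rank %d", k, rank))
  d <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (v[which.max(abs(v[, j])), j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  structure(list(
    scores = u %*% diag(d, k, k),
    loadings = v,
    explained_variance_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2),
    center = center,
    centered = centered,
    scaling = scaling,
    meta = meta),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", ncol(x$scores), " components, ",
      nrow(x$scores), " samples\n", sep = "")
  cat("  explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
             collapse = ", "), "\n")
  invisible(x)
}

#' Rotate a PCA score plane toward a target variable
#'
#' Within the plane of the first `k_plane` (default 2) components, finds
#' the in-plane direction whose scores correlate maximally (in absolute
#' value) with a per-sample target (developmental temperature); that
#' direction becomes the linear component and its in-plane orthogonal
#' complement the U-shape component. Loadings are rotated by the same
#' angle, so they remain orthonormal.
#'
#' @param p A `pca_model` with at least `k_plane` components.
#' @param target Per-sample numeric target (one value per score row).
#' @param k_plane Dimension of the rotation plane (only 2 is supported).
#' @return A `rotated_components` object with the rotation `angle`
#'   (radians), linear/U-shape scores and loadings, and `r_linear`, the
#'   correlation of the linear scores with the target.
#' @export
rotate_to_target <- function(p, target, k_plane = 2) {
  if (k_plane != 2) abort("only a 2-component rotation plane is supported")
  if (ncol(p$scores) < k_plane) abort("model has fewer components than k_plane")
  if (length(target) != nrow(p$scores))
    abort("`target` must have one value per sample")
  if (stats::sd(target) == 0) abort("zero-variance target")
  s <- p$scores[, 1:2, drop = FALSE]
  sc <- sweep(s, 2, colMeans(s))
  tc <- target - mean(target)
  # maximize (u' c)^2 / (u' V u) over unit u = (cos a, sin a):
  # solution u proportional to V^{-1} c (the regression direction).
  v <- crossprod(sc) / (nrow(sc) - 1)
  cv <- crossprod(sc, tc) / (nrow(sc) - 1)
  u <- solve(v, cv)
  u <- u / sqrt(sum(u^2))
  angle <- atan2(u[2], u[1])
  # columns are the optimal in-plane direction and its complement
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sr <- s %*% rot
  lr <- p$loadings[, 1:2, drop = FALSE] %*% rot
  r_lin <- stats::cor(sr[, 1], target)
  structure(list(angle = angle,
                 linear_scores = sr[, 1], linear_loadings = lr[, 1],
                 ushape_scores = sr[, 2], ushape_loadings = lr[, 2],
                 r_linear = r_lin, meta = p$meta),
            class = "rotated_components")
}

#' @export
print.rotated_components <- function(x, ...) {
  cat("<rotated_components> angle = ", sprintf("%.2f", x$angle * 180 / pi),
      " deg, r(linear, target) = ", sprintf("%.3f", x$r_linear), "\n",
      sep = "")
  invisible(x)
}
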