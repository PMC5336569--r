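# Orthogonal projections to latent structures (OPLS): one y-predictive
# component plus n_orth components orthogonal to y, following the
# orthogonal-filtering formulation (weight from X'y; each orthogonal weight
# is the part of the current X loading orthogonal to the predictive
# weight; X is deflated between extractions).

opls_matrix <- function(m) {
  if (inherits(m, "feature_matrix")) m$values else as.matrix(m)
}

#' Fit an OPLS model
#'
#' @param x Feature matrix (already centered/scaled upstream, e.g. by
#'   [pareto_scale()]) or a plain numeric matrix.
#' @param y Per-sample response with positive variance; centered
#'   internally.
#' @param n_orth Number of orthogonal components (>= 0). With
#'   `n_orth = 0` the predictive component equals single-component PLS.
#' @return An `opls_model` with predictive weights/scores/loadings,
#'   orthogonal components, `R2Y`, `R2X`, `A` (component descriptor
#'   `"1+n"`) and `N`.
#' @export
fit_opls <- function(x, y, n_orth = 0) {
  X <- opls_matrix(x)
  if (length(y) != nrow(X)) abort("`y` must have one value per sample")
  if (!all(is.finite(y)) || stats::sd(y) == 0)
    abort("`y` must be finite with positive variance")
  # exact rank is only worth computing when the matrix is small; for wide
  # matrices the dimension bound is used and degeneracy is caught during
  # extraction
  rank_x <- if (prod(dim(X)) <= 5e4) qr(X)$rank else min(dim(X))
  if (n_orth >= rank_x)
    abort(sprintf("n_orth = %d must be below rank(X) = %d", n_orth, rank_x))
  ym <- mean(y)
  yc <- y - ym
  E <- X
  ssx <- sum(X^2)
  W_o <- P_o <- T_o <- list()
  for (j in seq_len(n_orth)) {
    w <- as.numeric(crossprod(E, yc))
    w <- w / sqrt(sum(w^2))
    t <- as.numeric(E %*% w)
    p <- as.numeric(crossprod(E, t)) / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) abort("no orthogonal variation left to extract")
    wo <- wo / nwo
    to <- as.numeric(E %*% wo)
    po <- as.numeric(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    W_o[[j]] <- wo; P_o[[j]] <- po; T_o[[j]] <- to
  }
  w <- as.numeric(crossprod(E, yc))
  w <- w / sqrt(sum(w^2))
  t <- as.numeric(E %*% w)
  p <- as.numeric(crossprod(E, t)) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  yhat <- t * q + ym
  r2y <- 1 - sum((y - yhat)^2) / sum(yc^2)
  resid <- E - tcrossprod(t, p)
  r2x <- 1 - sum(resid^2) / ssx
  structure(list(
    A = sprintf("1+%d", n_orth), n_orth = n_orth, N = nrow(X),
    weights = w, scores = t, loadings = p, y_loading = q, y_mean = ym,
    orth_weights = W_o, orth_loadings = P_o, orth_scores = T_o,
    fitted = yhat, y = y, R2Y = r2y, R2X = r2x, Q2 = NA_real_),
    class = "opls_model")
}

#' Predict from an OPLS model
#'
#' New samples are deflated by each stored orthogonal component before the
#' predictive score and response are formed.
#'
#' @param object An `opls_model`.
#' @param newdata Matrix (or `feature_matrix`) on the same columns,
#'   preprocessed identically to the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xn <- opls_matrix(newdata)
  for (j in seq_along(object$orth_weights)) {
    to <- as.numeric(Xn %*% object$orth_weights[[j]])
    Xn <- Xn - tcrossprod(to, object$orth_loadings[[j]])
  }
  as.numeric(Xn %*% object$weights) * object$y_loading + object$y_mean
}

#' @export
print.opls_model <- function(x, ...) {
  cat("<opls_model> A = ", x$A, ", N = ", x$N,
      sprintf(", R2X = %.3f, R2Y = %.3f", x$R2X, x$R2Y),
      if (!is.na(x$Q2)) sprintf(", Q2 = %.3f", x$Q2), "\n", sep = "")
  invisible(x)
}

#' Leave-one-condition-out cross-validated Q2
#'
#' Every distinct group (a sex-by-temperature condition) is left out in
#' turn; centering/scaling is re-estimated on the training fold and applied
#' to the held-out samples before refitting and predicting. `Q2 = 1 -
#' PRESS / SS`, where SS accumulates the held-out squared deviations from
#' each fold's pooled training mean of `y`.
#'
#' @param x Unscaled feature matrix (e.g. normalized intensities).
#' @param y Per-sample response.
#' @param groups Per-sample condition labels; at least 3 distinct groups,
#'   none spanning all samples.
#' @param n_orth Orthogonal components, as in [fit_opls()].
#' @param scaling Fold-wise scaling recipe.
#' @return The Q2 value (numeric scalar).
#' @export
grouped_q2 <- function(x, y, groups, n_orth = 0,
                       scaling = c("pareto_centered", "pareto_uncentered",
                                   "none")) {
  scaling <- match.arg(scaling)
  X <- opls_matrix(x)
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 3) abort("need at least 3 distinct groups")
  press <- denom <- 0
  for (g in gl) {
    test <- groups == g
    if (all(test)) abort("a group contains all samples")
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (scaling != "none") {
      prm <- pareto_params(Xtr, centered = scaling == "pareto_centered")
      Xtr <- pareto_apply(Xtr, prm)
      Xte <- pareto_apply(Xte, prm)
    }
    fit <- fit_opls(Xtr, y[!test], n_orth = n_orth)
    pred <- predict(fit, Xte)
    press <- press + sum((y[test] - pred)^2)
    denom <- denom + sum((y[test] - mean(y[!test]))^2)
  }
  1 - press / denom
}
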