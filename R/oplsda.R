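# Discriminant OPLS over sex-by-temperature classes: multi-response OPLS
# against a class indicator matrix, with class-orthogonal components
# filtered out before the predictive scores are formed.

class_indicator <- function(classes) {
  classes <- as.character(classes)
  lv <- sort(unique(classes))
  Y <- vapply(lv, function(l) as.numeric(classes == l), numeric(length(classes)))
  colnames(Y) <- lv
  Y
}

#' Fit an OPLS-DA model over condition classes
#'
#' Builds a one-column-per-class indicator response, removes `n_orth`
#' components of X orthogonal to the class structure (each the part of the
#' leading X loading orthogonal to the current predictive weight space),
#' and extracts `n_pred` predictive components from the singular structure
#' of `X'Y`. X is column-centred internally and the means are stored, so
#' new samples are centred consistently at prediction time.
#'
#' @param x Scaled feature matrix or plain matrix.
#' @param classes Per-sample class labels; every class needs >= 2 samples.
#' @param n_pred Predictive components.
#' @param n_orth Orthogonal components.
#' @return An `oplsda_model` with per-sample predictive `scores`, the
#'   regression of the indicator on the scores, and bookkeeping fields.
#' @export
fit_oplsda <- function(x, classes, n_pred = 2, n_orth = 0) {
  X <- opls_matrix(x)
  classes <- as.character(classes)
  tab <- table(classes)
  if (length(tab) < 2) abort("need at least 2 classes")
  if (any(tab < 2)) abort("every class needs at least 2 samples")
  if (n_pred >= length(tab) + 1) n_pred <- length(tab) - 1
  Y <- class_indicator(classes)
  Ym <- colMeans(Y)
  Yc <- sweep(Y, 2, Ym)
  xm <- colMeans(X)
  E <- sweep(X, 2, xm)
  W_o <- P_o <- list()
  pred_weights <- function(E) {
    sv <- svd(crossprod(E, Yc), nu = n_pred, nv = 0)
    sv$u[, seq_len(n_pred), drop = FALSE]
  }
  for (j in seq_len(n_orth)) {
    W <- pred_weights(E)
    t1 <- as.numeric(E %*% W[, 1])
    p1 <- as.numeric(crossprod(E, t1)) / sum(t1^2)
    wo <- p1 - W %*% crossprod(W, p1)
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) abort("no class-orthogonal variation left to extract")
    wo <- wo / nwo
    to <- as.numeric(E %*% wo)
    po <- as.numeric(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    W_o[[j]] <- as.numeric(wo); P_o[[j]] <- po
  }
  W <- pred_weights(E)
  T_pred <- E %*% W
  # least-squares regression of the centered indicator on the scores
  Q <- solve(crossprod(T_pred), crossprod(T_pred, Yc))
  structure(list(
    A = sprintf("%d+%d", ncol(T_pred), n_orth),
    n_pred = ncol(T_pred), n_orth = n_orth, N = nrow(X),
    classes = classes, class_levels = colnames(Y),
    weights = W, scores = T_pred, q = Q, y_means = Ym, x_means = xm,
    orth_weights = W_o, orth_loadings = P_o),
    class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat("<oplsda_model> A = ", x$A, ", N = ", x$N, ", classes = ",
      length(x$class_levels), "\n", sep = "")
  invisible(x)
}

#' Predict class membership from an OPLS-DA model
#'
#' @param object An `oplsda_model`.
#' @param newdata Matrix on the same (identically preprocessed) columns.
#' @param type `"class"` for the arg-max class label, `"scores"` for
#'   predictive scores.
#' @param ... Unused.
#' @export
predict.oplsda_model <- function(object, newdata,
                                 type = c("class", "scores"), ...) {
  type <- match.arg(type)
  Xn <- sweep(opls_matrix(newdata), 2, object$x_means)
  for (j in seq_along(object$orth_weights)) {
    to <- as.numeric(Xn %*% object$orth_weights[[j]])
    Xn <- Xn - tcrossprod(to, object$orth_loadings[[j]])
  }
  Tn <- Xn %*% object$weights
  if (type == "scores") return(Tn)
  Yhat <- sweep(Tn %*% object$q, 2, object$y_means, "+")
  object$class_levels[max.col(Yhat, ties.method = "first")]
}

#' Cross-validated OPLS-DA class-prediction accuracy
#'
#' Random groups of samples are left out until every sample has been
#' predicted once; fold-wise scaling is re-estimated on each training
#' fold.
#'
#' @inheritParams fit_oplsda
#' @param folds Number of random folds.
#' @param seed Seed for the fold assignment.
#' @param scaling Fold-wise scaling recipe, as in [grouped_q2()].
#' @return Fraction of samples whose class is predicted correctly.
#' @export
oplsda_cv_accuracy <- function(x, classes, n_pred = 2, n_orth = 0,
                               folds = 7, seed = 1,
                               scaling = "pareto_centered") {
  X <- opls_matrix(x)
  classes <- as.character(classes)
  withr_seed(seed)
  # folds stratified by class so every training fold keeps >= 2 samples
  # of each class
  fold <- integer(nrow(X))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    fold[idx] <- sample(rep_len(sample.int(folds), length(idx)))
  }
  pred <- character(nrow(X))
  for (f in seq_len(folds)) {
    test <- fold == f
    if (length(unique(classes[!test])) < 2 || min(table(classes[!test])) < 2)
      abort("fold left a class with < 2 training samples")
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (scaling != "none") {
      prm <- pareto_params(Xtr, centered = scaling == "pareto_centered")
      Xtr <- pareto_apply(Xtr, prm)
      Xte <- pareto_apply(Xte, prm)
    }
    fit <- fit_oplsda(Xtr, classes[!test], n_pred = n_pred, n_orth = n_orth)
    pred[test] <- predict(fit, Xte)
  }
  mean(pred == classes)
}

#' Select the number of OPLS-DA orthogonal components by cross-validation
#'
#' @inheritParams oplsda_cv_accuracy
#' @param candidates Candidate `n_orth` values.
#' @return The candidate with the highest cross-validated accuracy (ties
#'   favor fewer components).
#' @export
select_oplsda_n_orth <- function(x, classes, n_pred = 2, candidates = 0:3,
                                 folds = 7, seed = 1) {
  acc <- vapply(candidates, function(no)
    oplsda_cv_accuracy(x, classes, n_pred = n_pred, n_orth = no,
                       folds = folds, seed = seed), numeric(1))
  candidates[which.max(acc)]
}
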