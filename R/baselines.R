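#' Fit per-gene Lasso regressions
#'
#' One L1-penalized least-squares problem per gene (gene columns of `Y`
#' are treated as independent responses):
#' \deqn{\min_w \frac{1}{2n}\|Xw + b - y\|_2^2 + \alpha \|w\|_1,}
#' with an unpenalized intercept and no predictor standardization (the
#' genotypes are already on \[0, 1\]). Solved by glmnet's coordinate
#' descent at the exact requested penalty; `alpha = 0` gives ordinary
#' least squares.
#'
#' @param X Genotype values (samples x markers), `genotype_matrix` or
#'   matrix.
#' @param Y Expression values (samples x genes), `expression_matrix` or
#'   matrix; a vector is treated as a single gene.
#' @param alpha Nonnegative regularization constant (the model-selection
#'   grid is `default_grid("lasso")`).
#' @return An object of class `lasso_fit`: coefficient matrix `w`
#'   (markers x genes), per-gene `intercepts`, and `alpha`.
#' @export
fit_lasso <- function(X, Y, alpha) {
  X <- values_of(X)
  if (is.numeric(Y) && !is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  Y <- values_of(Y)
  if (alpha < 0) stop("fit_lasso: alpha must be nonnegative")
  if (nrow(X) < 2L) stop("fit_lasso: need at least 2 samples")
  if (nrow(X) != nrow(Y)) stop("fit_lasso: sample counts differ")
  p <- ncol(X); G <- ncol(Y)
  w <- matrix(0, p, G, dimnames = list(colnames(X), colnames(Y)))
  b <- numeric(G)
  # decreasing path down to the requested penalty keeps coordinate descent
  # warm-started and accurate; coefficients are extracted exactly at alpha
  lam_hi <- max(alpha * 50, 1)
  lam_path <- exp(seq(log(lam_hi), log(max(alpha, 1e-6)), length.out = 30L))
  for (g in seq_len(G)) {
    fit <- glmnet::glmnet(X, Y[, g], family = "gaussian", alpha = 1,
                          lambda = lam_path, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-12, maxit = 1e6)
    # the exact refit interpolates over the lambda path and warns about
    # duplicated knots; the coefficients themselves are exact
    co <- suppressWarnings(as.numeric(glmnet::coef.glmnet(
      fit, s = alpha, exact = TRUE, x = X, y = Y[, g])))
    b[g] <- co[1L]
    w[, g] <- co[-1L]
  }
  structure(list(w = w, intercepts = b, alpha = alpha,
                 marker_ids = colnames(X), gene_ids = colnames(Y)),
            class = "lasso_fit")
}

#' Evaluate the Lasso objective
#'
#' \eqn{\frac{1}{2n}\|Xw + b - y\|_2^2 + \alpha\|w\|_1} for a single gene:
#' the quantity [fit_lasso()] minimizes, exposed so fits can be checked
#' for optimality directly.
#'
#' @param X Samples x markers matrix.
#' @param y Response vector.
#' @param w Coefficient vector.
#' @param b Intercept.
#' @param alpha Penalty constant.
#' @return Scalar objective value.
#' @export
lasso_objective <- function(X, y, w, b, alpha) {
  n <- nrow(X)
  sum((X %*% w + b - y)^2) / (2 * n) + alpha * sum(abs(w))
}

#' Smallest penalty that zeroes every Lasso coefficient
#'
#' For a centered response, all coefficients are exactly zero whenever
#' \eqn{\alpha \ge \max_j |x_j^T (y - \bar y)| / n}.
#'
#' @param X Samples x markers matrix.
#' @param y Response vector.
#' @return The null threshold.
#' @export
lasso_null_alpha <- function(X, y) {
  max(abs(crossprod(X, y - mean(y)))) / nrow(X)
}

#' @rdname fit_lasso
#' @param object A `lasso_fit`.
#' @param newdata Genotype values with the training marker count.
#' @param ... Unused.
#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  X <- values_of(newdata)
  if (ncol(X) != nrow(object$w)) {
    stop("predict: ", ncol(X), " markers supplied, model expects ", nrow(object$w))
  }
  sweep(X %*% object$w, 2L, object$intercepts, "+")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("Per-gene Lasso (alpha = ", x$alpha, "): ", nrow(x$w), " markers x ",
      ncol(x$w), " genes; ", sum(x$w != 0), " nonzero coefficients\n", sep = "")
  invisible(x)
}

#' Fit a per-gene Random-Forests regressor
#'
#' One seeded regression forest per gene; predictions are the ensemble
#' mean over trees. Tree hyperparameters other than the number of trees
#' follow the randomForest package defaults (mtry = p/3 for regression,
#' unlimited depth), which are echoed into evaluation reports.
#'
#' @param X Genotype values (samples x markers).
#' @param Y Expression values (samples x genes); a vector is one gene.
#' @param n_estimators Number of trees per forest (>= 1).
#' @param seed Integer seed; fits and predictions are reproducible.
#' @return An object of class `forest_fit`.
#' @export
fit_forest <- function(X, Y, n_estimators = 100L, seed = 1L) {
  X <- values_of(X)
  if (is.numeric(Y) && !is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  Y <- values_of(Y)
  if (n_estimators < 1L) stop("fit_forest: n_estimators must be >= 1")
  if (nrow(X) != nrow(Y)) stop("fit_forest: sample counts differ")
  set.seed(seed)
  forests <- lapply(seq_len(ncol(Y)), function(g) {
    randomForest::randomForest(x = X, y = Y[, g], ntree = n_estimators)
  })
  structure(list(forests = forests, n_estimators = n_estimators, seed = seed,
                 marker_ids = colnames(X), gene_ids = colnames(Y),
                 n_markers = ncol(X)),
            class = "forest_fit")
}

#' @rdname fit_forest
#' @param object A `forest_fit`.
#' @param newdata Genotype values with the training marker count.
#' @param ... Unused.
#' @export
predict.forest_fit <- function(object, newdata, ...) {
  X <- values_of(newdata)
  if (ncol(X) != object$n_markers) {
    stop("predict: ", ncol(X), " markers supplied, model expects ", object$n_markers)
  }
  out <- vapply(object$forests, function(f) {
    as.numeric(stats::predict(f, X))
  }, numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(rownames(X), object$gene_ids))
  out
}

#' @export
print.forest_fit <- function(x, ...) {
  cat("Per-gene Random Forests (", x$n_estimators, " trees): ",
      length(x$forests), " genes, ", x$n_markers, " markers\n", sep = "")
  invisible(x)
}

#' Predict expression from a fitted baseline or MLP-SAE model
#'
#' Uniform prediction surface over every model kind the evaluation harness
#' handles; dispatches to the model's `predict` method.
#'
#' @param model A `lasso_fit`, `forest_fit`, or `stacked_regressor`.
#' @param X Genotype values.
#' @return Predicted expression values (samples x genes).
#' @export
baseline_predict <- function(model, X) stats::predict(model, X)
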