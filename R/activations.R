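#' Logistic (sigmoid) activation
#'
#' Elementwise logistic function \eqn{(1 + e^{-v})^{-1}}, used for hidden
#' units operating on inputs scaled to \[0, 1\] (e.g. min-max scaled
#' genotypes). Overflow-safe for large \eqn{|v|}.
#'
#' @param v Numeric vector or matrix of pre-activations.
#' @return Values in (0, 1), same shape as `v`.
#' @seealso [tanh_act()], [activation()]
#' @export
#' @examples
#' logistic(0)      # 0.5
#' logistic(c(-2, 2))
logistic <- function(v) {
  out <- stats::plogis(as.vector(v))
  if (is.matrix(v)) dim(out) <- dim(v)
  out
}

#' Hyperbolic tangent activation
#'
#' Elementwise \eqn{\tanh(v)}, used for hidden units operating on values in
#' \[-1, 1\].
#'
#' @param v Numeric vector or matrix of pre-activations.
#' @return Values in (-1, 1), same shape as `v`.
#' @export
tanh_act <- function(v) tanh(v)

#' Activation function descriptor
#'
#' Bundles an activation's forward map with its derivative expressed in
#' terms of the forward *output* (the form backpropagation consumes:
#' logistic' = a(1-a), tanh' = 1-a^2, linear' = 1).
#'
#' @param name One of `"logistic"`, `"tanh"`, `"linear"`.
#' @return A list with elements `name`, `f` (forward map) and
#'   `df` (derivative as a function of the forward output).
#' @export
#' @examples
#' act <- activation("logistic")
#' a <- act$f(1.3)
#' act$df(a)   # equals a * (1 - a)
activation <- function(name = c("logistic", "tanh", "linear")) {
  name <- match.arg(name)
  switch(name,
    logistic = list(name = name, f = logistic, df = function(a) a * (1 - a)),
    tanh     = list(name = name, f = tanh_act, df = function(a) 1 - a^2),
    linear   = list(name = name, f = identity, df = function(a) {
      out <- rep(1, length(a)); if (is.matrix(a)) dim(out) <- dim(a); out
    })
  )
}

#' Squared-error reconstruction loss
#'
#' Per-sample squared reconstruction error \eqn{\|x - z\|^2}: the *sum* of
#' squared componentwise differences (no averaging). Mini-batch objectives
#' average this per-sample loss over the batch.
#'
#' @param x,z Numeric vectors of equal length (clean input and
#'   reconstruction).
#' @return A nonnegative scalar.
#' @export
squared_error <- function(x, z) {
  if (length(x) != length(z)) {
    stop("squared_error: length mismatch (", length(x), " vs ", length(z), ")")
  }
  sum((x - z)^2)
}

#' Binary cross-entropy reconstruction loss
#'
#' Standard binary cross-entropy
#' \eqn{-\sum_k [x_k \log z_k + (1-x_k)\log(1-z_k)]} for reconstructing a
#' binary (or \[0,1\]-valued) input from predicted probabilities.
#' Predictions are clipped into \[eps, 1-eps\] so the logs stay finite.
#'
#' @param x Numeric vector with entries in \[0, 1\].
#' @param z Numeric vector of predicted probabilities, same length as `x`.
#' @param eps Clipping constant for `z` (default 1e-12).
#' @return A nonnegative scalar.
#' @export
cross_entropy <- function(x, z, eps = 1e-12) {
  if (length(x) != length(z)) {
    stop("cross_entropy: length mismatch (", length(x), " vs ", length(z), ")")
  }
  z <- pmin(pmax(z, eps), 1 - eps)
  -sum(x * log(z) + (1 - x) * log(1 - z))
}

#' Mean squared error
#'
#' \eqn{\frac{1}{n}\sum_i (z_i - y_i)^2}. For matrix inputs the mean is
#' taken over all entries (samples and genes jointly), which is the scalar
#' used for model comparison and hyperparameter selection.
#'
#' @param z Predicted values (vector or matrix).
#' @param y Observed values, same shape as `z`.
#' @return A nonnegative scalar.
#' @export
#' @examples
#' mse(c(1, 2), c(0, 0))  # 2.5
mse <- function(z, y) {
  if (length(z) == 0L || length(y) == 0L) stop("mse: empty input")
  if (length(z) != length(y)) {
    stop("mse: length mismatch (", length(z), " vs ", length(y), ")")
  }
  mean((z - y)^2)
}
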