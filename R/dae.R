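#' Construct an untrained denoising auto-encoder
#'
#' One hidden layer with encoder weights `W_enc` (input_dim x hidden_dim),
#' decoder weights `W_dec` (hidden_dim x input_dim) and biases. Weights are
#' initialized uniformly on \[-r, r\] with
#' \eqn{r = \sqrt{6/(fan_{in}+fan_{out})}} (scaled by 4 for the logistic
#' activation, the classic heuristic); biases start at zero. The decoder's
#' output map is the identity under the squared-error loss and the logistic
#' under cross-entropy, so cross-entropy reconstructions are probabilities.
#'
#' @param input_dim Number of input units.
#' @param hidden_dim Number of hidden units (typically < `input_dim` for a
#'   compressed code).
#' @param activation Hidden activation: `"logistic"` (default), `"tanh"`,
#'   or `"linear"`.
#' @param loss Reconstruction loss: `"squared_error"` (default) or
#'   `"cross_entropy"`.
#' @param q Corruption level: the fraction of input coordinates masked to
#'   zero before encoding (default 0.2).
#' @param tied If `TRUE`, the decoder weight matrix is the transpose of the
#'   encoder's and the two are updated jointly. Default `FALSE`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `dae`.
#' @export
new_dae <- function(input_dim, hidden_dim, activation = "logistic",
                    loss = c("squared_error", "cross_entropy"),
                    q = 0.2, tied = FALSE, seed = 1L) {
  loss <- match.arg(loss)
  act <- activation(activation)
  if (q < 0 || q > 1) stop("corruption level q must lie in [0, 1]")
  set.seed(seed)
  r <- sqrt(6 / (input_dim + hidden_dim))
  if (act$name == "logistic") r <- 4 * r
  W_enc <- matrix(stats::runif(input_dim * hidden_dim, -r, r), input_dim, hidden_dim)
  W_dec <- if (tied) t(W_enc) else {
    matrix(stats::runif(hidden_dim * input_dim, -r, r), hidden_dim, input_dim)
  }
  structure(list(
    W_enc = W_enc, b_enc = rep(0, hidden_dim),
    W_dec = W_dec, b_dec = rep(0, input_dim),
    input_dim = as.integer(input_dim), hidden_dim = as.integer(hidden_dim),
    activation = act, loss = loss, q = q, tied = tied, seed = seed,
    trace = numeric(0)
  ), class = "dae")
}

#' Mask-corrupt an input
#'
#' Each coordinate is independently destroyed (set to zero) with
#' probability `q`, the classical masking corruption of denoising
#' auto-encoders. Draws come from R's current RNG stream, so the result is
#' deterministic given the stream state; `q = 0` and `q = 1` are handled
#' without consuming random numbers.
#'
#' @param x Numeric vector or matrix (rows = samples).
#' @param q Corruption level in \[0, 1\].
#' @return Corrupted copy of `x`, same shape.
#' @export
corrupt <- function(x, q) {
  if (q < 0 || q > 1) stop("corruption level q must lie in [0, 1]")
  if (q == 0) return(x)
  if (q == 1) return(x * 0)
  keep <- stats::runif(length(x)) >= q
  out <- x * keep
  out
}

#' Encode an input to its hidden code
#'
#' \eqn{Y = act(x W_{enc} + b_{enc})}. Accepts a single vector or a
#' samples-by-input matrix.
#'
#' @param dae A `dae`.
#' @param x Input vector of length `input_dim`, or matrix with
#'   `input_dim` columns.
#' @return Hidden code: vector of length `hidden_dim` or matrix with
#'   `hidden_dim` columns.
#' @export
encode <- function(dae, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != dae$input_dim) {
    stop("encode: input has ", ncol(X), " columns, expected ", dae$input_dim)
  }
  Y <- dae$activation$f(sweep(X %*% dae$W_enc, 2L, dae$b_enc, "+"))
  if (is.matrix(x)) Y else drop(Y)
}

#' Decode a hidden code into a reconstruction
#'
#' \eqn{Z = out(y W_{dec} + b_{dec})} where `out` is the logistic map when
#' the loss is cross-entropy and the identity under squared error.
#'
#' @param dae A `dae`.
#' @param y Hidden code vector of length `hidden_dim`, or matrix with
#'   `hidden_dim` columns.
#' @return Reconstruction with `input_dim` components per sample.
#' @export
reconstruct <- function(dae, y) {
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  if (ncol(Y) != dae$hidden_dim) {
    stop("reconstruct: code has ", ncol(Y), " columns, expected ", dae$hidden_dim)
  }
  Z <- sweep(Y %*% dae$W_dec, 2L, dae$b_dec, "+")
  if (dae$loss == "cross_entropy") Z <- logistic(Z)
  if (is.matrix(y)) Z else drop(Z)
}

#' Denoising reconstruction loss on a batch
#'
#' Corrupts each sample, encodes and decodes it, and averages the
#' per-sample reconstruction loss over the batch. The loss always compares
#' the reconstruction to the *clean* input, not the corrupted one — that is
#' what makes the objective denoising rather than plain auto-encoding.
#'
#' @param dae A `dae`.
#' @param X Batch matrix (samples x input_dim) or single vector.
#' @param seed Optional integer seed for the corruption draw; by default
#'   the current RNG stream is used.
#' @return Mean per-sample loss (nonnegative scalar).
#' @export
dae_loss <- function(dae, X, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  if (nrow(X) == 0L) stop("dae_loss: empty batch")
  Xc <- corrupt(X, dae$q)
  Z <- reconstruct(dae, encode(dae, Xc))
  Z <- if (is.matrix(Z)) Z else matrix(Z, nrow = 1L)
  lossfun <- if (dae$loss == "cross_entropy") cross_entropy else squared_error
  mean(vapply(seq_len(nrow(X)), function(i) lossfun(X[i, ], Z[i, ]), numeric(1)))
}

# Forward + backward pass with an explicit corruption mask (kept fixed so
# gradients can be checked by finite differences). Returns the batch-mean
# loss and gradients w.r.t. all four parameter arrays.
#' @keywords internal
.dae_forward_backward <- function(dae, X, mask) {
  n <- nrow(X)
  Xc <- X * mask
  A <- sweep(Xc %*% dae$W_enc, 2L, dae$b_enc, "+")
  H <- dae$activation$f(A)
  Zpre <- sweep(H %*% dae$W_dec, 2L, dae$b_dec, "+")
  if (dae$loss == "cross_entropy") {
    Z <- logistic(Zpre)
    Zc <- pmin(pmax(Z, 1e-12), 1 - 1e-12)
    loss <- mean(-rowSums(X * log(Zc) + (1 - X) * log(1 - Zc)))
    dZpre <- (Z - X) / n            # d(mean CE)/d pre-activation
  } else {
    Z <- Zpre
    loss <- mean(rowSums((X - Z)^2))
    dZpre <- 2 * (Z - X) / n
  }
  gW_dec <- crossprod(H, dZpre)
  gb_dec <- colSums(dZpre)
  dH <- dZpre %*% t(dae$W_dec)
  dA <- dH * dae$activation$df(H)
  gW_enc <- crossprod(Xc, dA)
  gb_enc <- colSums(dA)
  if (dae$tied) {
    g <- gW_enc + t(gW_dec)
    gW_enc <- g
    gW_dec <- t(g)
  }
  list(loss = loss,
       grads = list(W_enc = gW_enc, b_enc = gb_enc,
                    W_dec = gW_dec, b_dec = gb_dec))
}

#' Pretrain a denoising auto-encoder by mini-batch SGD
#'
#' Unsupervised layer-wise pretraining: each epoch shuffles the samples,
#' draws a fresh corruption mask per mini-batch, and takes a plain
#' stochastic-gradient step on the batch-mean reconstruction loss. After
#' each epoch the full-pass mean loss (with fresh corruption) is recorded.
#'
#' @param dae A `dae`.
#' @param X Training matrix (samples x input_dim), no missing values.
#' @param epochs Number of full passes (0 returns `dae` unchanged with an
#'   empty trace).
#' @param batch_size Mini-batch size (default 10; suited to panels of ~100
#'   samples).
#' @param learning_rate Positive SGD step size.
#' @param momentum Classical momentum coefficient in \[0, 1) (default 0,
#'   plain SGD).
#' @param seed Integer seed; the whole trajectory is deterministic given it.
#' @return The trained `dae`, with the per-epoch loss trace in `$trace`.
#' @export
pretrain <- function(dae, X, epochs = 100L, batch_size = 10L,
                     learning_rate = 0.01, momentum = 0, seed = 1L) {
  stopifnot(inherits(dae, "dae"))
  X <- values_of(X)
  if (nrow(X) == 0L) stop("pretrain: empty training matrix")
  if (anyNA(X)) stop("pretrain: training matrix contains missing values")
  if (learning_rate <= 0) stop("pretrain: learning_rate must be positive")
  if (epochs == 0L) { dae$trace <- numeric(0); return(dae) }
  set.seed(seed)
  n <- nrow(X)
  trace <- numeric(epochs)
  vel <- list(W_enc = dae$W_enc * 0, b_enc = dae$b_enc * 0,
              W_dec = dae$W_dec * 0, b_dec = dae$b_dec * 0)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      mask <- if (dae$q == 0) {
        matrix(1, nrow(Xb), ncol(Xb))
      } else if (dae$q == 1) {
        matrix(0, nrow(Xb), ncol(Xb))
      } else {
        matrix(as.numeric(stats::runif(length(Xb)) >= dae$q), nrow(Xb), ncol(Xb))
      }
      fb <- .dae_forward_backward(dae, Xb, mask)
      if (!is.finite(fb$loss)) {
        stop("pretrain: non-finite loss at epoch ", ep,
             " (learning rate ", learning_rate, ")")
      }
      for (nm in names(vel)) {
        vel[[nm]] <- momentum * vel[[nm]] - learning_rate * fb$grads[[nm]]
        dae[[nm]] <- dae[[nm]] + vel[[nm]]
      }
    }
    trace[ep] <- dae_loss(dae, X)
    if (!is.finite(trace[ep])) {
      stop("pretrain: non-finite loss at epoch ", ep,
           " (learning rate ", learning_rate, ")")
    }
  }
  dae$trace <- trace
  dae
}

#' @export
print.dae <- function(x, ...) {
  cat("Denoising auto-encoder ", x$input_dim, " -> ", x$hidden_dim,
      " (", x$activation$name, ", ", x$loss, ", q = ", x$q,
      if (x$tied) ", tied" else "", ")\n", sep = "")
  if (length(x$trace)) {
    cat("  pretrained ", length(x$trace), " epochs; final loss ",
        format(x$trace[length(x$trace)], digits = 6), "\n", sep = "")
  }
  invisible(x)
}
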