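#' Stack pretrained auto-encoders into a feedforward regressor
#'
#' Takes the *encoder* halves of an ordered list of pretrained denoising
#' auto-encoders as the hidden layers of a feedforward network (decoders
#' are discarded) and attaches a freshly initialized linear multi-output
#' regression head predicting all genes jointly. The canonical
#' configuration has two hidden layers (a four-layer network: input, two
#' auto-encoder hidden layers, linear output), but any chain length >= 1 is
#' accepted.
#'
#' @param daes List of `dae` objects whose dimensions chain: the hidden
#'   dimension of layer i must equal the input dimension of layer i+1.
#' @param n_genes Number of output units (genes).
#' @param seed Seed for the output-layer initialization.
#' @param dropout Optional dropout specification from [dropout_spec()];
#'   `NULL` disables dropout.
#' @return An object of class `stacked_regressor`.
#' @export
stack_regressor <- function(daes, n_genes, seed = 1L, dropout = NULL) {
  if (inherits(daes, "dae")) daes <- list(daes)
  stopifnot(length(daes) >= 1L, all(vapply(daes, inherits, logical(1), "dae")))
  for (i in seq_len(length(daes) - 1L)) {
    if (daes[[i]]$hidden_dim != daes[[i + 1L]]$input_dim) {
      stop("stack_regressor: layer ", i, " outputs ", daes[[i]]$hidden_dim,
           " units but layer ", i + 1L, " expects ", daes[[i + 1L]]$input_dim)
    }
  }
  hidden <- lapply(daes, function(d) {
    list(W = d$W_enc, b = d$b_enc, activation = d$activation)
  })
  last_dim <- daes[[length(daes)]]$hidden_dim
  set.seed(seed)
  r <- sqrt(6 / (last_dim + n_genes))
  structure(list(
    hidden = hidden,
    output_W = matrix(stats::runif(last_dim * n_genes, -r, r), last_dim, n_genes),
    output_b = rep(0, n_genes),
    input_dim = as.integer(daes[[1L]]$input_dim),
    n_genes = as.integer(n_genes),
    dropout = dropout,
    seed = seed
  ), class = "stacked_regressor")
}

#' Dropout specification
#'
#' Retention probabilities for the dropout variant: each unit is kept
#' independently with probability `p` during training; at inference the
#' weights fed by a unit class are scaled by its retention probability
#' (mean-network inference, exact for linear layers). `p = 1` disables
#' dropout for that unit class.
#'
#' @param p_hidden Retention probability for hidden units, in (0, 1\].
#'   Default 0.5, the standard near-optimal choice.
#' @param p_input Retention probability for input units, in (0, 1\].
#'   Default 0.9 (input retention is usually kept close to 1).
#' @return A list of class `dropout_spec`.
#' @export
dropout_spec <- function(p_hidden = 0.5, p_input = 0.9) {
  if (p_hidden <= 0 || p_hidden > 1 || p_input <= 0 || p_input > 1) {
    stop("retention probabilities must lie in (0, 1]")
  }
  structure(list(p_hidden = p_hidden, p_input = p_input), class = "dropout_spec")
}

#' @keywords internal
.drop_p <- function(model) {
  if (is.null(model$dropout)) list(p_hidden = 1, p_input = 1) else model$dropout
}

# Draw Bernoulli retention masks for one batch; p = 1 draws nothing so that
# a dropout model with full retention consumes the same RNG stream as a
# model without dropout (their trajectories must be bitwise identical).
#' @keywords internal
.draw_masks <- function(model, n) {
  p <- .drop_p(model)
  masks <- list(input = NULL, hidden = vector("list", length(model$hidden)))
  if (p$p_input < 1) {
    masks$input <- matrix(as.numeric(stats::runif(n * model$input_dim) < p$p_input),
                          n, model$input_dim)
  }
  if (p$p_hidden < 1) {
    for (l in seq_along(model$hidden)) {
      h <- ncol(model$hidden[[l]]$W)
      masks$hidden[[l]] <- matrix(as.numeric(stats::runif(n * h) < p$p_hidden), n, h)
    }
  }
  masks
}

# Forward pass keeping intermediate activations (post-mask) for backprop.
# masks = NULL means deterministic mean-network inference: every weight
# matrix is scaled by the retention probability of the units feeding it.
#' @keywords internal
.mlp_forward_full <- function(model, X, masks = NULL) {
  p <- .drop_p(model)
  infer <- is.null(masks)
  A <- X
  if (!infer && !is.null(masks$input)) A <- A * masks$input
  acts <- vector("list", length(model$hidden))
  for (l in seq_along(model$hidden)) {
    lay <- model$hidden[[l]]
    W <- lay$W
    if (infer) W <- W * (if (l == 1L) p$p_input else p$p_hidden)
    H <- lay$activation$f(sweep(A %*% W, 2L, lay$b, "+"))
    if (!infer && !is.null(masks$hidden[[l]])) H <- H * masks$hidden[[l]]
    acts[[l]] <- H
    A <- H
  }
  W_out <- if (infer) model$output_W * p$p_hidden else model$output_W
  Z <- sweep(A %*% W_out, 2L, model$output_b, "+")
  list(input = if (!infer && !is.null(masks$input)) X * masks$input else X,
       acts = acts, Z = Z)
}

#' Forward pass of a stacked regressor
#'
#' In `infer` mode the pass is deterministic: each weight matrix is scaled
#' by the retention probability of the units feeding it (the mean-network
#' approximation to averaging all thinned sub-networks; exact for linear
#' layers). In `train` mode independent Bernoulli retention masks are
#' applied to the input and to each hidden activation, drawn from the
#' current RNG stream. The output layer is linear in both modes.
#'
#' @param model A `stacked_regressor`.
#' @param X Samples-by-input matrix (or single vector).
#' @param mode `"infer"` (default) or `"train"`.
#' @return Predicted expression batch (samples x genes).
#' @export
forward <- function(model, X, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  vec <- !is.matrix(X)
  X <- if (vec) matrix(X, nrow = 1L) else X
  if (ncol(X) != model$input_dim) {
    stop("forward: input has ", ncol(X), " columns, expected ", model$input_dim)
  }
  masks <- if (mode == "train") .draw_masks(model, nrow(X)) else NULL
  Z <- .mlp_forward_full(model, X, masks)$Z
  if (vec) drop(Z) else Z
}

# Backprop of the grand-mean squared prediction error through all layers.
# Masks (possibly NULL entries) are held fixed within the call.
#' @keywords internal
.mlp_forward_backward <- function(model, X, Y, masks) {
  fw <- .mlp_forward_full(model, X, masks)
  n <- nrow(X)
  G <- ncol(Y)
  resid <- fw$Z - Y
  loss <- mean(resid^2)
  dZ <- 2 * resid / (n * G)
  L <- length(model$hidden)
  last <- if (L > 0L) fw$acts[[L]] else fw$input
  g_out_W <- crossprod(last, dZ)
  g_out_b <- colSums(dZ)
  gh <- vector("list", L)
  dH <- dZ %*% t(model$output_W)
  for (l in rev(seq_len(L))) {
    lay <- model$hidden[[l]]
    H <- fw$acts[[l]]
    if (!is.null(masks$hidden[[l]])) dH <- dH * masks$hidden[[l]]
    # H already carries the mask; where masked, H = 0 and df may be nonzero
    # for tanh/linear, hence the explicit mask on dH above.
    dA <- dH * lay$activation$df(H)
    below <- if (l > 1L) fw$acts[[l - 1L]] else fw$input
    gh[[l]] <- list(W = crossprod(below, dA), b = colSums(dA))
    dH <- dA %*% t(lay$W)
  }
  list(loss = loss, grads = list(hidden = gh, output_W = g_out_W, output_b = g_out_b))
}

#' Fine-tune a stacked regressor by backpropagation
#'
#' Supervised end-to-end training: mini-batch SGD on the mean squared
#' prediction error (averaged over batch samples and genes),
#' backpropagated through the output layer and all pretrained hidden
#' layers. Dropout masks (if enabled) are resampled per batch. After each
#' epoch the training and validation MSE are computed in infer mode; the
#' returned model carries the parameter state with the lowest validation
#' MSE seen (early stopping), and training halts once the validation MSE
#' has not improved for `patience` consecutive epochs.
#'
#' @param model A `stacked_regressor`.
#' @param X,Y Training genotype and expression matrices (samples x
#'   markers, samples x genes).
#' @param X_valid,Y_valid Optional validation split used for early
#'   stopping and best-state selection; when absent, the final state is
#'   returned and `patience` is ignored.
#' @param epochs Maximum number of epochs (default 500).
#' @param batch_size Mini-batch size (default 10).
#' @param learning_rate Positive SGD step size.
#' @param momentum Classical momentum coefficient in \[0, 1) (default 0,
#'   plain SGD).
#' @param seed Integer seed; the trajectory is deterministic given it.
#' @param patience Early-stopping patience in epochs (default 25).
#' @return The trained `stacked_regressor` with a `trace` matrix
#'   (columns `train_mse`, `valid_mse`) and `best_epoch`.
#' @export
finetune <- function(model, X, Y, X_valid = NULL, Y_valid = NULL,
                     epochs = 500L, batch_size = 10L, learning_rate = 0.1,
                     momentum = 0, seed = 1L, patience = 25L) {
  stopifnot(inherits(model, "stacked_regressor"))
  X <- values_of(X); Y <- values_of(Y)
  if (nrow(X) != nrow(Y)) stop("finetune: X and Y sample counts differ")
  if (!is.null(X_valid)) {
    X_valid <- values_of(X_valid); Y_valid <- values_of(Y_valid)
    if (nrow(X_valid) != nrow(Y_valid)) stop("finetune: validation sample counts differ")
  }
  if (learning_rate <= 0) stop("finetune: learning_rate must be positive")
  if (epochs == 0L) {
    model$trace <- matrix(numeric(0), 0L, 2L,
                          dimnames = list(NULL, c("train_mse", "valid_mse")))
    return(model)
  }
  set.seed(seed)
  n <- nrow(X)
  vel <- list(hidden = lapply(model$hidden, function(l)
                list(W = l$W * 0, b = l$b * 0)),
              output_W = model$output_W * 0, output_b = model$output_b * 0)
  has_valid <- !is.null(X_valid)
  trace <- matrix(NA_real_, epochs, 2L,
                  dimnames = list(NULL, c("train_mse", "valid_mse")))
  best <- list(mse = Inf, model = model, epoch = 0L)
  stall <- 0L
  last_ep <- 0L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      masks <- .draw_masks(model, nrow(Xb))
      fb <- .mlp_forward_backward(model, Xb, Yb, masks)
      if (!is.finite(fb$loss)) {
        stop("finetune: non-finite loss at epoch ", ep,
             " (learning rate ", learning_rate, ")")
      }
      for (l in seq_along(model$hidden)) {
        vel$hidden[[l]]$W <- momentum * vel$hidden[[l]]$W -
          learning_rate * fb$grads$hidden[[l]]$W
        vel$hidden[[l]]$b <- momentum * vel$hidden[[l]]$b -
          learning_rate * fb$grads$hidden[[l]]$b
        model$hidden[[l]]$W <- model$hidden[[l]]$W + vel$hidden[[l]]$W
        model$hidden[[l]]$b <- model$hidden[[l]]$b + vel$hidden[[l]]$b
      }
      vel$output_W <- momentum * vel$output_W - learning_rate * fb$grads$output_W
      vel$output_b <- momentum * vel$output_b - learning_rate * fb$grads$output_b
      model$output_W <- model$output_W + vel$output_W
      model$output_b <- model$output_b + vel$output_b
    }
    trace[ep, "train_mse"] <- mse(forward(model, X), Y)
    if (has_valid) {
      vm <- mse(forward(model, X_valid), Y_valid)
      trace[ep, "valid_mse"] <- vm
      if (vm < best$mse) {
        best <- list(mse = vm, model = model, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    if (!all(is.finite(trace[ep, "train_mse"]))) {
      stop("finetune: non-finite loss at epoch ", ep,
           " (learning rate ", learning_rate, ")")
    }
    last_ep <- ep
    if (has_valid && stall >= patience) break
  }
  out <- if (has_valid) best$model else model
  out$trace <- trace[seq_len(last_ep), , drop = FALSE]
  out$best_epoch <- if (has_valid) best$epoch else last_ep
  out
}

#' @rdname forward
#' @param object A `stacked_regressor`.
#' @param newdata New genotype matrix (samples x markers).
#' @param ... Unused.
#' @export
predict.stacked_regressor <- function(object, newdata, ...) {
  forward(object, values_of(newdata), mode = "infer")
}

#' @export
print.stacked_regressor <- function(x, ...) {
  dims <- c(x$input_dim, vapply(x$hidden, function(l) ncol(l$W), numeric(1)), x$n_genes)
  cat("Stacked auto-encoder regressor: ", paste(dims, collapse = " -> "), "\n", sep = "")
  p <- .drop_p(x)
  if (!is.null(x$dropout)) {
    cat("  dropout: p_hidden = ", p$p_hidden, ", p_input = ", p$p_input, "\n", sep = "")
  }
  invisible(x)
}
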