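#' Fit an MLP-SAE gene-expression predictor
#'
#' The package's main fitting function. Builds a feedforward regressor
#' whose hidden layers are pretrained greedily as denoising auto-encoders
#' (each layer learns to reconstruct the clean output of the layer below
#' from a mask-corrupted copy), stacks the encoders with a linear
#' multi-output regression head, and fine-tunes the whole network
#' end-to-end by backpropagation on the mean squared prediction error.
#' Optional dropout regularizes the fine-tuning stage.
#'
#' @param geno Training genotypes: `genotype_matrix` or numeric matrix
#'   (samples x markers), preprocessed to \[0, 1\] with no missing values
#'   (see [impute_and_scale()]).
#' @param expr Training expression: `expression_matrix` or numeric matrix
#'   (samples x genes) with no missing values (see [drop_na_genes()]).
#' @param hidden Integer vector of hidden-layer widths, outermost first.
#'   Default `c(500, 100)`, sized for a yeast-scale panel of ~3000 markers;
#'   use smaller widths for smaller marker sets.
#' @param activation Hidden activation, `"logistic"` (default, matching
#'   \[0,1\]-scaled genotypes), `"tanh"`, or `"linear"`.
#' @param dae_loss Pretraining reconstruction loss, `"squared_error"`
#'   (default) or `"cross_entropy"`.
#' @param q Corruption level for pretraining (default 0.2).
#' @param dropout `NULL` (default, no dropout), `TRUE` for
#'   [dropout_spec()] defaults, or a `dropout_spec`.
#' @param pretrain_epochs,pretrain_lr,pretrain_batch_size Pretraining
#'   schedule (defaults 100 epochs, rate 0.01, batches of 10).
#' @param epochs,learning_rate,batch_size Fine-tuning schedule (defaults:
#'   at most 500 epochs, rate 0.1, batches of 10).
#' @param momentum Classical momentum for fine-tuning (default 0, plain
#'   SGD); `pretrain_momentum` is its pretraining counterpart.
#' @param pretrain_momentum Momentum for the pretraining stage (default 0).
#' @param patience Early-stopping patience on validation MSE (default 25
#'   epochs; only active when a validation split is given).
#' @param X_valid,Y_valid Optional validation split for early stopping.
#' @param seed Integer seed governing initialization, corruption, batch
#'   order and dropout; fits are deterministic given it.
#' @return An object of class `c("mlp_sae", "stacked_regressor")` with the
#'   fitted network, pretraining and fine-tuning loss traces, the full
#'   configuration echo, and training fit summaries. Supports `predict`,
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, and `plot`.
#' @export
#' @examples
#' spec <- cross_sim_spec(n_samples = 60, n_markers = 30, n_genes = 5,
#'                        causal_per_gene = 3, noise_sd = 0.3, seed = 1)
#' g <- simulate_genotypes(spec)
#' e <- simulate_expression(g, spec)$expression
#' fit <- mlp_sae(impute_and_scale(g), e, hidden = c(16, 8),
#'                pretrain_epochs = 5, epochs = 20, seed = 1)
#' predict(fit, impute_and_scale(g))[1:2, ]
mlp_sae <- function(geno, expr, hidden = c(500, 100),
                    activation = "logistic",
                    dae_loss = c("squared_error", "cross_entropy"),
                    q = 0.2, dropout = NULL,
                    pretrain_epochs = 100L, pretrain_lr = 0.01,
                    pretrain_batch_size = 10L, pretrain_momentum = 0,
                    epochs = 500L, learning_rate = 0.1, batch_size = 10L,
                    momentum = 0, patience = 25L, X_valid = NULL,
                    Y_valid = NULL, seed = 1L) {
  dae_loss <- match.arg(dae_loss)
  X <- values_of(geno)
  Y <- values_of(expr)
  if (nrow(X) != nrow(Y)) stop("mlp_sae: genotype and expression sample counts differ")
  if (anyNA(X) || anyNA(Y)) {
    stop("mlp_sae: missing values present; run impute_and_scale()/drop_na_genes() first")
  }
  if (isTRUE(dropout)) dropout <- dropout_spec()
  cfg <- list(
    hidden = hidden, activation = activation, dae_loss = dae_loss, q = q,
    dropout_p_hidden = if (is.null(dropout)) 1 else dropout$p_hidden,
    dropout_p_input = if (is.null(dropout)) 1 else dropout$p_input,
    pretrain_epochs = pretrain_epochs, pretrain_lr = pretrain_lr,
    pretrain_batch_size = pretrain_batch_size,
    pretrain_momentum = pretrain_momentum,
    epochs = epochs, learning_rate = learning_rate, batch_size = batch_size,
    momentum = momentum, patience = patience, seed = seed,
    n_train = nrow(X), n_markers = ncol(X), n_genes = ncol(Y)
  )
  # greedy layer-wise pretraining: each auto-encoder reconstructs the
  # (clean) representation produced by the stack below it
  daes <- vector("list", length(hidden))
  inp <- X
  for (l in seq_along(hidden)) {
    d <- new_dae(ncol(inp), hidden[l], activation = activation,
                 loss = dae_loss, q = q, seed = seed + l)
    daes[[l]] <- pretrain(d, inp, epochs = pretrain_epochs,
                          batch_size = pretrain_batch_size,
                          learning_rate = pretrain_lr,
                          momentum = pretrain_momentum, seed = seed + 100L + l)
    inp <- encode(daes[[l]], inp)
  }
  model <- stack_regressor(daes, n_genes = ncol(Y), seed = seed + 200L,
                           dropout = dropout)
  model <- finetune(model, X, Y, X_valid = X_valid, Y_valid = Y_valid,
                    epochs = epochs, batch_size = batch_size,
                    learning_rate = learning_rate, momentum = momentum,
                    seed = seed + 300L, patience = patience)
  model$pretrain_traces <- lapply(daes, function(d) d$trace)
  model$config <- cfg
  model$marker_ids <- colnames(X)
  model$gene_ids <- colnames(Y)
  fitted_vals <- forward(model, X)
  model$fitted_values <- fitted_vals
  model$train_residuals <- Y - fitted_vals
  model$train_mse <- mse(fitted_vals, Y)
  model$call <- match.call()
  class(model) <- c("mlp_sae", "stacked_regressor")
  model
}

#' @export
print.mlp_sae <- function(x, ...) {
  cfg <- x$config
  dims <- c(cfg$n_markers, cfg$hidden, cfg$n_genes)
  cat("MLP-SAE gene-expression predictor\n")
  cat("  architecture: ", paste(dims, collapse = " -> "),
      "  (", cfg$activation, " hidden units, linear output)\n", sep = "")
  cat("  pretraining:  ", cfg$pretrain_epochs, " epochs, rate ", cfg$pretrain_lr,
      ", corruption q = ", cfg$q, ", loss = ", cfg$dae_loss, "\n", sep = "")
  cat("  fine-tuning:  ", nrow(x$trace), " epochs run (cap ", cfg$epochs,
      "), rate ", cfg$learning_rate, ", batch ", cfg$batch_size, "\n", sep = "")
  if (cfg$dropout_p_hidden < 1 || cfg$dropout_p_input < 1) {
    cat("  dropout:      p_hidden = ", cfg$dropout_p_hidden,
        ", p_input = ", cfg$dropout_p_input, "\n", sep = "")
  }
  cat("  training MSE: ", format(x$train_mse, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mlp_sae <- function(object, ...) {
  cfg <- object$config
  out <- list(
    config = cfg,
    epochs_run = nrow(object$trace),
    best_epoch = object$best_epoch,
    train_mse = object$train_mse,
    valid_mse = if (ncol(object$trace) >= 2 && any(is.finite(object$trace[, "valid_mse"])))
      min(object$trace[, "valid_mse"], na.rm = TRUE) else NA_real_,
    pretrain_final_losses = vapply(object$pretrain_traces, function(tr)
      if (length(tr)) tr[length(tr)] else NA_real_, numeric(1))
  )
  class(out) <- "summary.mlp_sae"
  out
}

#' @export
print.summary.mlp_sae <- function(x, ...) {
  cfg <- x$config
  cat("MLP-SAE fit summary\n")
  cat("  network:   ", paste(c(cfg$n_markers, cfg$hidden, cfg$n_genes), collapse = " -> "), "\n")
  cat("  pretrain final reconstruction losses:",
      paste(format(x$pretrain_final_losses, digits = 5), collapse = ", "), "\n")
  cat("  fine-tune epochs:", x$epochs_run, "(best", x$best_epoch, ")\n")
  cat("  training MSE: ", format(x$train_mse, digits = 6), "\n")
  if (is.finite(x$valid_mse)) cat("  best validation MSE:", format(x$valid_mse, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.mlp_sae <- function(object, ...) {
  co <- object$output_W
  dimnames(co) <- list(NULL, object$gene_ids)
  co
}

#' @export
fitted.mlp_sae <- function(object, ...) object$fitted_values

#' @export
residuals.mlp_sae <- function(object, ...) object$train_residuals

#' Plot MLP-SAE training traces
#'
#' Training (and validation, when present) MSE per fine-tuning epoch.
#'
#' @param x An `mlp_sae` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mlp_sae <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(seq_len(nrow(tr)), tr, type = "l", lty = 1,
                    col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "MSE", ...)
  graphics::legend("topright", legend = colnames(tr), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
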