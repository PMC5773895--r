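make_net <- function(dims, acts = NULL, seed = 1, dropout = NULL, q = 0) {
  L <- length(dims) - 2L
  if (is.null(acts)) acts <- rep("logistic", L)
  daes <- lapply(seq_len(L), function(l) {
    new_dae(dims[l], dims[l + 1L], acts[l], "squared_error", q = q,
            seed = seed + l)
  })
  stack_regressor(daes, n_genes = dims[length(dims)], seed = seed + 99,
                  dropout = dropout)
}

test_that("stacking checks the dimension chain and discards decoders", {
  d1 <- new_dae(100, 32, seed = 1)
  d2 <- new_dae(32, 16, seed = 2)
  m <- stack_regressor(list(d1, d2), n_genes = 50, seed = 3)
  expect_identical(m$input_dim, 100L)
  expect_identical(dim(m$output_W), c(16L, 50L))
  expect_identical(dim(m$hidden[[1]]$W), c(100L, 32L))
  expect_identical(m$hidden[[2]]$W, d2$W_enc)

  bad <- new_dae(20, 16, seed = 4)
  expect_error(stack_regressor(list(d1, bad), n_genes = 5),
               "layer 1 outputs 32 units but layer 2 expects 20")
})

test_that("the stacked forward pass equals the composed encoders plus linear head", {
  d1 <- new_dae(6, 4, "logistic", seed = 5)
  d2 <- new_dae(4, 3, "tanh", seed = 6)
  m <- stack_regressor(list(d1, d2), n_genes = 2, seed = 7)
  set.seed(8)
  X <- matrix(runif(18), 3, 6)
  composed <- sweep(encode(d2, encode(d1, X)) %*% m$output_W, 2, m$output_b, "+")
  expect_equal(forward(m, X), composed, tolerance = 1e-12)
  expect_equal(forward(m, X), oracle_forward(m, X), tolerance = 1e-10)

  zero <- make_net(c(5, 4, 3, 2), seed = 9)
  for (l in seq_along(zero$hidden)) {
    zero$hidden[[l]]$W[] <- 0; zero$hidden[[l]]$b[] <- 0
  }
  zero$output_W[] <- 0; zero$output_b[] <- 0
  expect_equal(forward(zero, matrix(rnorm(10), 2, 5)), matrix(0, 2, 2))
  expect_error(forward(m, matrix(0, 2, 5)), "expected 6")
})

test_that("disabled dropout leaves train and infer modes identical", {
  m <- make_net(c(5, 4, 3, 2), seed = 10, dropout = dropout_spec(1, 1))
  X <- matrix(runif(20), 4, 5)
  set.seed(1)
  expect_identical(forward(m, X, "train"), forward(m, X, "infer"))
})

test_that("weight-scaled inference matches the Monte-Carlo dropout mean on a linear net", {
  m <- make_net(c(5, 4, 3, 2), acts = c("linear", "linear"), seed = 11,
                dropout = dropout_spec(0.5, 0.5))
  # positive weights keep the mean output large relative to the Monte-Carlo
  # standard error, so the 1% comparison is well conditioned
  for (l in seq_along(m$hidden)) m$hidden[[l]]$W <- abs(m$hidden[[l]]$W)
  m$output_W <- abs(m$output_W)
  set.seed(30)
  x <- matrix(runif(5, 0.5, 1.5), 1, 5)
  infer <- forward(m, x, "infer")
  set.seed(99)
  acc <- matrix(0, 1, 2)
  for (i in 1:20000) acc <- acc + forward(m, x, "train")
  mc <- acc / 20000
  expect_lt(max(abs(mc - infer) / abs(infer)), 0.01)
})

test_that("end-to-end fine-tuning gradients match finite differences", {
  set.seed(12)
  X <- matrix(runif(18), 3, 6)
  Y <- matrix(rnorm(6), 3, 2)
  for (acts in list(c("logistic", "logistic"), c("tanh", "tanh"))) {
    for (drop in list(NULL, dropout_spec(0.5, 0.8))) {
      m <- make_net(c(6, 4, 3, 2), acts = acts, seed = 13, dropout = drop)
      set.seed(14)
      masks <- mlpsae:::.draw_masks(m, nrow(X))
      fb <- mlpsae:::.mlp_forward_backward(m, X, Y, masks)
      num <- central_diff(function(th) {
        mlpsae:::.mlp_forward_backward(mlp_set_params(m, th), X, Y, masks)$loss
      }, mlp_get_params(m))
      expect_lt(max_rel_err(mlp_flat_grads(fb$grads), num, floor = 1e-6), 1e-5)
    }
  }
})

test_that("finetune is a no-op at 0 epochs and learns noiseless linear data", {
  m <- make_net(c(6, 4, 3, 2), seed = 15)
  X <- matrix(runif(60), 10, 6)
  Y <- matrix(rnorm(20), 10, 2)
  same <- finetune(m, X, Y, epochs = 0, learning_rate = 0.1)
  expect_identical(mlp_get_params(same), mlp_get_params(m))

  set.seed(16)
  Xl <- matrix(rbinom(200 * 30, 1, 0.5), 200, 30)
  B <- matrix(rnorm(30 * 5, 0, 0.5), 30, 5)
  Yl <- Xl %*% B  # noiseless linear map
  d1 <- pretrain(new_dae(30, 20, "tanh", seed = 17), Xl,
                 epochs = 30, learning_rate = 0.01, seed = 19)
  d2 <- pretrain(new_dae(20, 10, "tanh", seed = 18), encode(d1, Xl),
                 epochs = 30, learning_rate = 0.01, seed = 19)
  mm <- stack_regressor(list(d1, d2), n_genes = 5, seed = 20)
  fit <- finetune(mm, Xl, Yl, epochs = 400, learning_rate = 0.1, seed = 21)
  expect_lt(fit$trace[nrow(fit$trace), "train_mse"], 1e-2)
})

test_that("prediction is deterministic and batch-consistent", {
  m <- make_net(c(5, 4, 3, 2), seed = 22, dropout = dropout_spec(0.5, 0.9))
  X <- matrix(runif(25), 5, 5)
  p1 <- predict(m, X)
  p2 <- predict(m, X)
  expect_identical(p1, p2)
  expect_equal(drop(predict(m, X[3, , drop = FALSE])), p1[3, ], tolerance = 1e-15)
})

test_that("full-retention dropout training is bitwise identical to no dropout", {
  X <- matrix(runif(80), 16, 5)
  Y <- matrix(rnorm(32), 16, 2)
  plain <- make_net(c(5, 4, 3, 2), seed = 23)
  dp1 <- make_net(c(5, 4, 3, 2), seed = 23, dropout = dropout_spec(1, 1))
  f1 <- finetune(plain, X, Y, epochs = 20, learning_rate = 0.1, seed = 24)
  f2 <- finetune(dp1, X, Y, epochs = 20, learning_rate = 0.1, seed = 24)
  expect_identical(mlp_get_params(f1), mlp_get_params(f2))
  expect_identical(f1$trace, f2$trace)
})

test_that("early stopping returns the best validation state", {
  set.seed(25)
  X <- matrix(runif(200), 40, 5)
  B <- matrix(rnorm(10), 5, 2)
  Y <- X %*% B + matrix(rnorm(80, 0, 0.2), 40, 2)
  m <- make_net(c(5, 4, 3, 2), seed = 26)
  fit <- finetune(m, X[1:30, ], Y[1:30, ], X[31:40, ], Y[31:40, ],
                  epochs = 120, learning_rate = 0.1, seed = 27, patience = 15)
  vm <- fit$trace[, "valid_mse"]
  best_mse <- mse(forward(fit, X[31:40, ]), Y[31:40, ])
  expect_equal(best_mse, min(vm), tolerance = 1e-12)
  expect_lte(best_mse, vm[length(vm)])
})

test_that("mlp_sae fits, exposes methods, and round-trips through serialization", {
  set.seed(28)
  X <- matrix(rbinom(60 * 20, 1, 0.5) * 1.0, 60, 20,
              dimnames = list(sprintf("s%02d", 1:60), sprintf("m%02d", 1:20)))
  Y <- X[, 1:4] %*% matrix(rnorm(16), 4, 4) + matrix(rnorm(240, 0, 0.3), 60, 4)
  colnames(Y) <- paste0("g", 1:4); rownames(Y) <- rownames(X)
  fit <- mlp_sae(X, Y, hidden = c(10, 6), pretrain_epochs = 10, epochs = 40,
                 learning_rate = 0.1, seed = 29)
  expect_s3_class(fit, "mlp_sae")
  expect_identical(dim(fitted(fit)), dim(Y))
  expect_equal(residuals(fit), Y - fitted(fit))
  expect_identical(dim(coef(fit)), c(6L, 4L))
  expect_output(print(fit), "architecture: 20 -> 10 -> 6 -> 4")
  expect_output(print(summary(fit)), "training MSE")

  path <- tempfile(fileext = ".txt")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(predict(back, X), unname(predict(fit, X)), tolerance = 1e-15,
               ignore_attr = TRUE)

  # refit with the same seed is deterministic
  fit2 <- mlp_sae(X, Y, hidden = c(10, 6), pretrain_epochs = 10, epochs = 40,
                  learning_rate = 0.1, seed = 29)
  expect_identical(mlp_get_params(fit), mlp_get_params(fit2))
})
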