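# Independent loop-based oracles and finite-difference machinery used to
# check the vectorized implementation. Everything here is deliberately
# naive (explicit loops, closed forms) so it cannot share a bug with the
# code under test.

loop_squared_error <- function(x, z) {
  s <- 0
  for (k in seq_along(x)) s <- s + (x[k] - z[k])^2
  s
}

loop_cross_entropy <- function(x, z, eps = 1e-12) {
  s <- 0
  for (k in seq_along(x)) {
    zk <- min(max(z[k], eps), 1 - eps)
    s <- s - (x[k] * log(zk) + (1 - x[k]) * log(1 - zk))
  }
  s
}

loop_mse <- function(z, y) {
  s <- 0
  for (i in seq_along(z)) s <- s + (z[i] - y[i])^2
  s / length(z)
}

loop_pearson_r2 <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  (num / sqrt(da * db))^2
}

# Hand-composed forward pass: explicit per-sample, per-unit loops.
oracle_forward <- function(model, X) {
  n <- nrow(X)
  out <- matrix(0, n, model$n_genes)
  for (i in seq_len(n)) {
    a <- X[i, ]
    for (l in seq_along(model$hidden)) {
      lay <- model$hidden[[l]]
      h <- numeric(ncol(lay$W))
      for (j in seq_along(h)) h[j] <- sum(a * lay$W[, j]) + lay$b[j]
      a <- lay$activation$f(h)
    }
    for (g in seq_len(model$n_genes)) {
      out[i, g] <- sum(a * model$output_W[, g]) + model$output_b[g]
    }
  }
  out
}

# Flatten/restore all parameters of a dae or stacked_regressor so losses
# can be finite-differenced parameter by parameter.
dae_get_params <- function(d) c(d$W_enc, d$b_enc, d$W_dec, d$b_dec)

dae_set_params <- function(d, th) {
  i <- 0L
  take <- function(k) { out <- th[i + seq_len(k)]; i <<- i + k; out }
  d$W_enc <- matrix(take(length(d$W_enc)), nrow(d$W_enc))
  d$b_enc <- take(length(d$b_enc))
  d$W_dec <- matrix(take(length(d$W_dec)), nrow(d$W_dec))
  d$b_dec <- take(length(d$b_dec))
  d
}

dae_flat_grads <- function(gr) c(gr$W_enc, gr$b_enc, gr$W_dec, gr$b_dec)

mlp_get_params <- function(m) {
  th <- numeric(0)
  for (l in seq_along(m$hidden)) th <- c(th, m$hidden[[l]]$W, m$hidden[[l]]$b)
  c(th, m$output_W, m$output_b)
}

mlp_set_params <- function(m, th) {
  i <- 0L
  take <- function(k) { out <- th[i + seq_len(k)]; i <<- i + k; out }
  for (l in seq_along(m$hidden)) {
    m$hidden[[l]]$W <- matrix(take(length(m$hidden[[l]]$W)), nrow(m$hidden[[l]]$W))
    m$hidden[[l]]$b <- take(length(m$hidden[[l]]$b))
  }
  m$output_W <- matrix(take(length(m$output_W)), nrow(m$output_W))
  m$output_b <- take(length(m$output_b))
  m
}

mlp_flat_grads <- function(gr) {
  th <- numeric(0)
  for (l in seq_along(gr$hidden)) th <- c(th, gr$hidden[[l]]$W, gr$hidden[[l]]$b)
  c(th, gr$output_W, gr$output_b)
}

central_diff <- function(loss_at, theta, eps = 1e-6) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- theta[i] + eps
    tm <- theta; tm[i] <- theta[i] - eps
    g[i] <- (loss_at(tp) - loss_at(tm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b, floor = 1e-8) max(abs(a - b) / pmax(abs(b), floor))

# Cyclic coordinate descent for min 1/(2n)||Xw + b - y||^2 + a||w||_1 with
# an unpenalized intercept: the independent Lasso solver.
cd_lasso <- function(X, y, alpha, iters = 2000L, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  w <- rep(0, p); b <- mean(y)
  zj <- colSums(X^2) / n
  for (it in seq_len(iters)) {
    w_old <- w
    r <- y - X %*% w - b
    b <- b + mean(r)
    r <- y - X %*% w - b
    for (j in seq_len(p)) {
      if (zj[j] == 0) next
      rho <- sum(X[, j] * (r + X[, j] * w[j])) / n
      wj <- sign(rho) * max(abs(rho) - alpha, 0) / zj[j]
      r <- r - X[, j] * (wj - w[j])
      w[j] <- wj
    }
    if (max(abs(w - w_old)) < tol) break
  }
  list(w = as.numeric(w), b = as.numeric(b))
}

# Small random fixtures shared across tests.
random_genotype_matrix <- function(n, p, seed, missing_rate = 0) {
  set.seed(seed)
  v <- matrix(rbinom(n * p, 1, 0.5) * 1.0, n, p,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("m%04d", 1:p)))
  if (missing_rate > 0) v[runif(n * p) < missing_rate] <- NA_real_
  structure(list(values = v, sample_ids = rownames(v), marker_ids = colnames(v),
                 missing_mask = is.na(v)), class = "genotype_matrix")
}

make_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
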