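test_that("k-fold partitions are balanced, disjoint, complete and seeded", {
  f <- kfold_indices(10, 5, seed = 1)
  expect_length(f, 5)
  expect_true(all(lengths(f) == 2))
  expect_setequal(unlist(f), 1:10)

  f11 <- kfold_indices(11, 5, seed = 2)
  expect_setequal(sort(lengths(f11)), c(2, 2, 2, 2, 3))
  expect_identical(kfold_indices(20, 4, seed = 3), kfold_indices(20, 4, seed = 3))
  expect_error(kfold_indices(3, 5), "exceeds")
  expect_error(kfold_indices(10, 1), ">= 2")
})

test_that("cv_select reproduces a hand-unrolled two-fold computation", {
  set.seed(4)
  X <- matrix(rbinom(12 * 4, 1, 0.5) * 1.0, 12, 4)
  y <- drop(X %*% c(1, -1, 0, 0)) + rnorm(12, 0, 0.1)
  grid <- c(0.05, 0.3)
  res <- cv_select("lasso", grid, X, y, k = 2, seed = 5)
  folds <- kfold_indices(12, 2, seed = 5)
  manual <- sapply(grid, function(a) {
    mean(sapply(1:2, function(i) {
      hold <- folds[[i]]
      fit <- fit_lasso(X[-hold, ], y[-hold], a)
      mse(predict(fit, X[hold, , drop = FALSE]), y[hold])
    }))
  })
  expect_equal(res$table$cv_mean_mse, manual, tolerance = 1e-10)
  expect_equal(res$selected, grid[which.min(manual)])
})

test_that("selection picks the single candidate and is permutation-invariant", {
  set.seed(6)
  X <- matrix(rbinom(30 * 6, 1, 0.5) * 1.0, 30, 6)
  y <- drop(X %*% c(1, 1, 0, 0, 0, 0)) + rnorm(30, 0, 0.1)
  one <- cv_select("lasso", 0.2, X, y, k = 3, seed = 7)
  expect_equal(one$selected, 0.2)

  g1 <- c(0.05, 0.2, 0.5)
  g2 <- c(0.5, 0.05, 0.2)
  s1 <- cv_select("lasso", g1, X, y, k = 3, seed = 7)
  s2 <- cv_select("lasso", g2, X, y, k = 3, seed = 7)
  expect_equal(s1$selected, s2$selected)
  expect_identical(s2$table$candidate, g2)  # table rows follow the given grid
})

test_that("on noiseless linear data the least-shrinkage penalty wins the CV", {
  set.seed(8)
  X <- matrix(rbinom(60 * 10, 1, 0.5) * 1.0, 60, 10)
  Y <- X %*% matrix(rnorm(20), 10, 2)  # exactly linear, no noise
  res <- cv_select("lasso", default_grid("lasso"), X, Y, k = 5, seed = 9)
  expect_equal(res$selected, 0.05)
  expect_equal(which.min(res$table$cv_mean_mse), 1L)
})

test_that("constant predictions score the held-out target variance", {
  # a null model that always predicts the training mean has CV MSE equal to
  # the mean per-fold population variance of the held-out targets
  set.seed(10)
  y <- rnorm(24, 5, 2)
  folds <- kfold_indices(24, 4, seed = 11)
  for (i in 1:4) {
    hold <- folds[[i]]
    pred <- rep(mean(y[hold]), length(hold))  # constant at the fold mean
    expect_equal(mse(pred, y[hold]),
                 mean((y[hold] - mean(y[hold]))^2), tolerance = 1e-12)
  }
})

test_that("per-gene R2 is the squared Pearson correlation, affine-invariant", {
  set.seed(12)
  Y <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  expect_equal(unname(per_gene_r2(Y, Y)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(per_gene_r2(Y, 2.5 * Y - 7)), rep(1, 3), tolerance = 1e-12)

  P <- matrix(rnorm(90), 30, 3)
  r2 <- per_gene_r2(Y, P)
  for (g in 1:3) {
    expect_equal(unname(r2[g]), loop_pearson_r2(Y[, g], P[, g]), tolerance = 1e-10)
  }
  const <- Y; const[, 2] <- 3
  expect_true(is.na(per_gene_r2(const, P)[2]))
  expect_error(per_gene_r2(Y[1:2, ], P[1:2, ]), "3 samples")
})

test_that("R2 binning follows the report bins and reconciles totals", {
  counts <- bin_r2(c(0.04, 0.06, 0.75))
  expect_identical(unname(counts[1:9]), c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_identical(names(counts)[1], "(0,0.05]")
  expect_identical(sum(counts), 3L)

  empty <- bin_r2(numeric(0))
  expect_true(all(empty == 0))

  set.seed(13)
  r2 <- c(runif(50), NA, NA, 0, -0.2)
  counts <- bin_r2(r2)
  expect_identical(sum(counts), length(r2))  # every gene lands somewhere
  expect_gte(counts[["le0_or_undefined"]], 4L)
  # boundary values land in the closed-right bin
  expect_identical(unname(bin_r2(0.05)[1]), 1L)
  expect_identical(unname(bin_r2(1)[["(0.9,1]"]]), 1L)
})

test_that("track export is gene-major, complete and round-trips exactly", {
  set.seed(14)
  Yt <- matrix(rnorm(6), 3, 2,
               dimnames = list(paste0("s", 1:3), c("gA", "gB")))
  Yp <- Yt + 0.1
  path <- tempfile(fileext = ".tsv")
  export_tracks(Yt, Yp, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$gene_id, rep(c("gA", "gB"), each = 3))
  expect_equal(tab$true, unname(c(Yt[, 1], Yt[, 2])), tolerance = 1e-15)
  expect_equal(tab$predicted, unname(c(Yp[, 1], Yp[, 2])), tolerance = 1e-15)

  export_tracks(Yt, Yp, path, gene_subset = "gB")
  expect_identical(nrow(read.delim(path)), 3L)
  expect_error(export_tracks(Yt, Yp, path, gene_subset = "nope"), "unknown gene")
})

test_that("reports echo configuration and rerun byte-identically", {
  set.seed(15)
  X <- matrix(rbinom(40 * 6, 1, 0.5) * 1.0, 40, 6)
  y <- drop(X %*% c(1, -1, 0, 0, 0, 0)) + rnorm(40, 0, 0.2)
  cv <- cv_select("lasso", c(0.05, 0.2), X, y, k = 2, seed = 16)
  fit <- fit_lasso(X, y, cv$selected)
  r2 <- per_gene_r2(matrix(y, ncol = 1), predict(fit, X))
  rep1 <- evaluation_report("lasso", cv, test_mse = 0.123, r2 = r2,
                            config = list(seed = 16, q = 0.2, hidden = c(500, 100)))
  d1 <- tempfile(); d2 <- tempfile()
  write_report(rep1, d1); write_report(rep1, d2)
  expect_identical(readLines(file.path(d1, "report.txt")),
                   readLines(file.path(d2, "report.txt")))
  txt <- readLines(file.path(d1, "report.txt"))
  expect_true(any(grepl("config_row\tq\t0.2", txt, fixed = TRUE)))
  expect_true(any(grepl("config_row\thidden\t500", txt)))
  js <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(js$selected_hyperparameter, cv$selected)
})
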