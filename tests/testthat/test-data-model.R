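test_that("read_matrix parses identifiers, values and missingness", {
  path <- make_tsv(c(
    "sample_id\tm1\tm2",
    "s1\t0\t1",
    "s2\t1\tNA",
    "s3\t0\t0"))
  g <- read_matrix(path, "genotype")
  expect_s3_class(g, "genotype_matrix")
  expect_identical(g$sample_ids, c("s1", "s2", "s3"))
  expect_identical(g$marker_ids, c("m1", "m2"))
  expect_identical(sum(g$missing_mask), 1L)
  expect_true(g$missing_mask["s2", "m2"])
  expect_equal(g$values["s3", "m1"], 0)
})

test_that("read_matrix rejects duplicates and ragged rows with line numbers", {
  dup <- make_tsv(c("sample_id\tm1\tm1", "s1\t0\t1"))
  expect_error(read_matrix(dup, "genotype"), "duplicate feature id")
  dup_s <- make_tsv(c("sample_id\tm1", "s1\t0", "s1\t1"))
  expect_error(read_matrix(dup_s, "genotype"), "duplicate sample id")
  ragged <- make_tsv(c("sample_id\tm1\tm2", "s1\t0\t1", "s2\t1"))
  expect_error(read_matrix(ragged, "genotype"), "ragged row at line 3")
  bad <- make_tsv(c("sample_id\tm1", "s1\tx"))
  expect_error(read_matrix(bad, "genotype"), "non-numeric")
})

test_that("write-then-read round trip reproduces values exactly", {
  set.seed(42)
  v <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:6)))
  v[c(3, 17)] <- NA
  path <- tempfile(fileext = ".tsv")
  write_matrix(v, path)
  back <- read_matrix(path, "expression")
  expect_identical(back$values, v)
  expect_identical(sum(back$missing_mask), 2L)
})

test_that("drop_na_genes removes exactly the contaminated columns in order", {
  v <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("s", 1:4), c("g1", "g2", "g3")))
  clean <- mlpsae:::.new_typed_matrix(v, "expression")
  expect_identical(drop_na_genes(clean)$values, v)

  v2 <- v; v2[2, 2] <- NA
  e <- mlpsae:::.new_typed_matrix(v2, "expression")
  out <- drop_na_genes(e)
  expect_identical(out$gene_ids, c("g1", "g3"))
  expect_identical(out$values, v2[, c("g1", "g3")])  # surviving values untouched
  expect_identical(out$sample_ids, e$sample_ids)

  all_na <- mlpsae:::.new_typed_matrix(
    matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("g1", "g2"))), "expression")
  expect_error(drop_na_genes(all_na), "all genes")
})

test_that("a 7085-gene panel with 474 contaminated columns reduces to 6611", {
  # the classic array panel dimensions: dropping every NA-carrying gene
  # from 7085 leaves 6611
  set.seed(11)
  n <- 8
  v <- matrix(rnorm(n * 7085), n, 7085,
              dimnames = list(paste0("s", 1:n), sprintf("g%04d", 1:7085)))
  na_cols <- sample(7085, 474)
  for (j in na_cols) v[sample(n, 1), j] <- NA
  e <- mlpsae:::.new_typed_matrix(v, "expression")
  expect_identical(ncol(drop_na_genes(e)$values), 6611L)
})

test_that("impute_and_scale fills column means then maps onto [0,1]", {
  v <- cbind(a = c(0, 1, NA), b = c(2, 4, 6), c = c(5, 5, 5))
  rownames(v) <- paste0("s", 1:3)
  g <- mlpsae:::.new_typed_matrix(v, "genotype")
  out <- impute_and_scale(g)
  expect_equal(out$values[, "a"], c(s1 = 0, s2 = 1, s3 = 0.5))  # mean of {0,1}
  expect_equal(out$values[, "b"], c(s1 = 0, s2 = 0.5, s3 = 1))
  expect_equal(out$values[, "c"], c(s1 = 0, s2 = 0, s3 = 0))    # constant -> 0
  expect_false(any(out$missing_mask))

  v2 <- cbind(a = c(NA_real_, NA_real_), b = c(1, 2))
  rownames(v2) <- c("s1", "s2")
  expect_error(impute_and_scale(mlpsae:::.new_typed_matrix(v2, "genotype")), "'a'")
})

test_that("impute_and_scale matches a per-column oracle and is idempotent", {
  g <- random_genotype_matrix(30, 15, seed = 5, missing_rate = 0.1)
  g$values <- g$values * 3 + 1  # arbitrary affine genotype coding
  g$values[g$missing_mask] <- NA
  out <- impute_and_scale(g)
  for (j in seq_len(ncol(g$values))) {
    col <- g$values[, j]
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    rng <- max(col) - min(col)
    expected <- if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
    expect_equal(unname(out$values[, j]), unname(expected), tolerance = 1e-12)
  }
  expect_true(all(out$values >= 0 & out$values <= 1))
  twice <- impute_and_scale(out)
  expect_equal(twice$values, out$values, tolerance = 1e-15)
})

test_that("split_samples partitions deterministically with near-exact sizes", {
  sp <- split_samples(10, c(0.6, 0.2, 0.2), seed = 1)
  expect_length(sp$train_idx, 6)
  expect_length(sp$validation_idx, 2)
  expect_length(sp$test_idx, 2)
  all_idx <- c(sp$train_idx, sp$validation_idx, sp$test_idx)
  expect_setequal(all_idx, 1:10)
  expect_identical(anyDuplicated(all_idx), 0L)

  sp2 <- split_samples(10, c(0.6, 0.2, 0.2), seed = 1)
  expect_identical(sp, sp2)

  sp3 <- split_samples(112, c(0.6, 0.2, 0.2), seed = 3)
  sizes <- lengths(sp3[c("train_idx", "validation_idx", "test_idx")])
  expect_identical(sum(sizes), 112L)
  expect_true(all(abs(sizes - 112 * c(0.6, 0.2, 0.2)) < 1))

  expect_error(split_samples(2, c(0.6, 0.2, 0.2), 1), "at least 3")
  expect_error(split_samples(10, c(0.5, 0.2, 0.2), 1), "sum to 1")
  # with different seeds the index sets differ (n large enough)
  a <- split_samples(40, seed = 1)$train_idx
  b <- split_samples(40, seed = 2)$train_idx
  expect_false(identical(a, b))
})
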