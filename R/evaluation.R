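#' Deterministic k-fold partition
#'
#' Splits `1:n_samples` into `k` disjoint folds whose sizes differ by at
#' most one, on a seeded random permutation.
#'
#' @param n_samples Number of samples.
#' @param k Number of folds (>= 2, <= `n_samples`).
#' @param seed Integer seed.
#' @return A list of `k` integer index vectors.
#' @export
kfold_indices <- function(n_samples, k = 5L, seed = 1L) {
  if (k < 2L) stop("kfold_indices: k must be >= 2")
  if (k > n_samples) stop("kfold_indices: k exceeds the number of samples")
  set.seed(seed)
  perm <- sample.int(n_samples)
  sizes <- rep(n_samples %/% k, k)
  extra <- n_samples %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
}

#' Default hyperparameter grids
#'
#' The candidate grids used for model selection: Lasso penalty
#' `alpha` in \{0.05, 0.1, 0.2, ..., 0.8\}, Random-Forests tree counts
#' \{10, 20, ..., 70, 100, 150, 200\}, and MLP-SAE learning rates
#' \{0.1, 0.01, 0.001, 1e-4, 1e-5\}.
#'
#' @param model_kind One of `"lasso"`, `"forest"`, `"mlp_sae"`,
#'   `"mlp_sae_dropout"`.
#' @return Numeric vector of candidate values.
#' @export
default_grid <- function(model_kind = c("lasso", "forest", "mlp_sae",
                                        "mlp_sae_dropout")) {
  model_kind <- match.arg(model_kind)
  switch(model_kind,
    lasso = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
    forest = c(10, 20, 30, 40, 50, 60, 70, 100, 150, 200),
    c(0.1, 0.01, 0.001, 0.0001, 0.00001)
  )
}

# Fit one model of the given kind at one hyperparameter value.
#' @keywords internal
.fit_model <- function(model_kind, X, Y, hyper, seed, fit_args = list()) {
  switch(model_kind,
    lasso = fit_lasso(X, Y, alpha = hyper),
    forest = fit_forest(X, Y, n_estimators = as.integer(hyper), seed = seed),
    mlp_sae = do.call(mlp_sae, c(list(geno = X, expr = Y,
                                      learning_rate = hyper, seed = seed),
                                 fit_args)),
    mlp_sae_dropout = {
      if (is.null(fit_args$dropout)) fit_args$dropout <- dropout_spec()
      do.call(mlp_sae, c(list(geno = X, expr = Y,
                              learning_rate = hyper, seed = seed),
                         fit_args))
    },
    stop("unknown model kind: ", model_kind)
  )
}

#' Cross-validated hyperparameter selection
#'
#' For each candidate value, fits the model on k-1 folds and scores the
#' held fold by the grand-mean MSE over all genes and samples; the
#' candidate with the lowest mean held-fold MSE is selected. Ties are
#' broken toward the smaller candidate value (less complexity: smaller
#' penalty is listed first in the grid convention, fewer trees, smaller
#' learning rate); the selection is invariant to grid ordering. Candidates
#' whose training diverges are scored `Inf` and excluded; if every
#' candidate fails, an error is raised.
#'
#' @param model_kind One of `"lasso"`, `"forest"`, `"mlp_sae"`,
#'   `"mlp_sae_dropout"`.
#' @param grid Numeric vector of candidate hyperparameter values
#'   (default [default_grid()] for the kind).
#' @param X,Y Training genotype and expression values.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold partition and the fits.
#' @param fit_args Extra arguments passed to the fitter (e.g. `hidden`,
#'   `epochs` for the MLP kinds).
#' @return A list with `selected` (the chosen value) and `table`
#'   (data.frame of candidate and mean CV MSE, ordered as the grid).
#' @export
cv_select <- function(model_kind, grid = default_grid(model_kind), X, Y,
                      k = 5L, seed = 1L, fit_args = list()) {
  if (length(grid) == 0L) stop("cv_select: empty grid")
  X <- values_of(X)
  if (is.numeric(Y) && !is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  Y <- values_of(Y)
  folds <- kfold_indices(nrow(X), k = k, seed = seed)
  mean_mse <- vapply(grid, function(h) {
    fold_mse <- vapply(seq_len(k), function(i) {
      hold <- folds[[i]]
      tryCatch({
        fit <- .fit_model(model_kind, X[-hold, , drop = FALSE],
                          Y[-hold, , drop = FALSE], h, seed = seed,
                          fit_args = fit_args)
        mse(stats::predict(fit, X[hold, , drop = FALSE]), Y[hold, , drop = FALSE])
      }, error = function(e) Inf)
    }, numeric(1))
    mean(fold_mse)
  }, numeric(1))
  if (all(!is.finite(mean_mse))) stop("cv_select: every candidate failed to train")
  ord <- order(grid)                      # tie-break toward the smaller value
  finite <- is.finite(mean_mse[ord])
  sel <- grid[ord][finite][which.min(mean_mse[ord][finite])]
  list(selected = sel,
       table = data.frame(candidate = grid, cv_mean_mse = mean_mse))
}

#' Per-gene squared Pearson correlation
#'
#' For each gene, the squared Pearson correlation across samples between
#' true and predicted expression. This measures tracking of expression
#' changes, not absolute agreement (it is invariant to affine rescaling of
#' the predictions). Genes whose true or predicted values have zero
#' variance get `NA` (undefined) and are excluded from binning.
#'
#' @param Y_true,Y_pred Matching samples x genes matrices with >= 3
#'   samples.
#' @return Named numeric vector of per-gene R-squared values.
#' @export
per_gene_r2 <- function(Y_true, Y_pred) {
  Y_true <- values_of(Y_true); Y_pred <- values_of(Y_pred)
  if (!all(dim(Y_true) == dim(Y_pred))) stop("per_gene_r2: shape mismatch")
  if (nrow(Y_true) < 3L) stop("per_gene_r2: need at least 3 samples")
  r2 <- vapply(seq_len(ncol(Y_true)), function(g) {
    yt <- Y_true[, g]; yp <- Y_pred[, g]
    if (anyNA(yt) || anyNA(yp)) return(NA_real_)
    if (stats::sd(yt) == 0 || stats::sd(yp) == 0) return(NA_real_)
    stats::cor(yt, yp)^2
  }, numeric(1))
  names(r2) <- colnames(Y_true)
  r2
}

#' Bin per-gene R-squared values
#'
#' Counts genes in the standard report bins `(0,0.05], (0.05,0.1],
#' (0.1,0.2], ..., (0.7,0.8]`, plus overflow bins `(0.8,0.9]` and
#' `(0.9,1]` and a reconciliation bucket for genes whose R-squared is
#' undefined or not above 0, so the counts always total the gene count.
#'
#' @param r2 Numeric vector of per-gene R-squared values (may contain
#'   `NA`).
#' @return Named integer vector of counts, report bins first and the
#'   reconciliation bucket last.
#' @export
bin_r2 <- function(r2) {
  breaks <- c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
  labs <- paste0("(", utils::head(breaks, -1L), ",", breaks[-1L], "]")
  counts <- integer(length(labs))
  ok <- !is.na(r2) & r2 > 0
  if (any(ok)) {
    cutted <- cut(r2[ok], breaks = breaks, labels = labs, right = TRUE)
    counts <- as.integer(table(cutted))
  }
  names(counts) <- labs
  c(counts, "le0_or_undefined" = sum(!ok))
}

#' Export predicted-vs-true expression tracks
#'
#' Writes a long-format tab-delimited file (`gene_id`, `sample_id`,
#' `true`, `predicted`), gene-major with samples in input order, suitable
#' for plotting expression tracks of all or selected genes.
#'
#' @param Y_true,Y_pred Matching samples x genes matrices with dimnames.
#' @param path Output path.
#' @param gene_subset Optional character vector of gene ids to export.
#' @return `path`, invisibly.
#' @export
export_tracks <- function(Y_true, Y_pred, path, gene_subset = NULL) {
  Y_true <- values_of(Y_true); Y_pred <- values_of(Y_pred)
  if (!all(dim(Y_true) == dim(Y_pred))) stop("export_tracks: shape mismatch")
  genes <- colnames(Y_true)
  samples <- rownames(Y_true)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(Y_true)))
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(Y_true)))
  if (!is.null(gene_subset)) {
    unknown <- setdiff(gene_subset, genes)
    if (length(unknown)) stop("export_tracks: unknown gene id '", unknown[1L], "'")
    sel <- match(gene_subset, genes)
  } else {
    sel <- seq_along(genes)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("gene_id\tsample_id\ttrue\tpredicted", con)
  for (g in sel) {
    writeLines(sprintf("%s\t%s\t%.17g\t%.17g",
                       genes[g], samples, Y_true[, g], Y_pred[, g]), con)
  }
  invisible(path)
}

#' Assemble an evaluation report
#'
#' Collects the model-selection table, the selected hyperparameter, the
#' test-set MSE, per-gene R-squared values with their bin counts, and a
#' full configuration echo (every default made explicit) into a single
#' object that can be printed or written to disk with [write_report()].
#'
#' @param model_kind Model kind string.
#' @param cv Result of [cv_select()].
#' @param test_mse Held-out test MSE.
#' @param r2 Per-gene R-squared vector on the test set.
#' @param config Named list echoing the complete run configuration.
#' @return An object of class `evaluation_report`.
#' @export
evaluation_report <- function(model_kind, cv, test_mse, r2, config) {
  structure(list(
    model_kind = model_kind,
    cv_table = cv$table,
    selected = cv$selected,
    test_mse = test_mse,
    r2 = r2,
    r2_bins = bin_r2(r2),
    config = config
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report:", x$model_kind, "\n")
  cat("  selected hyperparameter:", format(x$selected, digits = 6), "\n")
  cat("  test MSE:", format(x$test_mse, digits = 6), "\n")
  cat("  CV table:\n")
  print(x$cv_table, row.names = FALSE)
  cat("  R2 bins:\n")
  print(x$r2_bins)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits a human-readable `report.txt` and a machine-readable
#' `report.json` into `dir`. Both echo the full configuration, and neither
#' contains timestamps, so reruns with identical inputs are byte-identical.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- file.path(dir, "report.txt")
  con <- file(txt, open = "wb")
  writeLines(c(
    paste0("model_kind\t", report$model_kind),
    paste0("selected_hyperparameter\t", sprintf("%.17g", report$selected)),
    paste0("test_mse\t", sprintf("%.17g", report$test_mse)),
    "",
    "cv_table\tcandidate\tcv_mean_mse",
    sprintf("cv_row\t%.17g\t%.17g",
            report$cv_table$candidate, report$cv_table$cv_mean_mse),
    "",
    "r2_bins\tbin\tcount",
    sprintf("r2_bin\t%s\t%d", names(report$r2_bins), report$r2_bins),
    "",
    "config\tkey\tvalue",
    sprintf("config_row\t%s\t%s", names(report$config),
            vapply(report$config, function(v) paste(format(v, digits = 17),
                                                    collapse = ","), character(1)))
  ), con)
  close(con)
  json <- list(
    model_kind = report$model_kind,
    selected_hyperparameter = report$selected,
    test_mse = report$test_mse,
    cv_table = report$cv_table,
    r2_bins = as.list(report$r2_bins),
    config = report$config
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
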