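#' @keywords internal
.new_typed_matrix <- function(values, kind) {
  cls <- if (kind == "genotype") "genotype_matrix" else "expression_matrix"
  obj <- list(
    values       = values,
    sample_ids   = rownames(values),
    missing_mask = is.na(values)
  )
  if (kind == "genotype") obj$marker_ids <- colnames(values) else obj$gene_ids <- colnames(values)
  structure(obj, class = cls)
}

#' @keywords internal
.feature_ids <- function(x) if (inherits(x, "genotype_matrix")) x$marker_ids else x$gene_ids

#' Extract the numeric matrix from a typed matrix (or pass a matrix through)
#' @param x A `genotype_matrix`, `expression_matrix`, or plain numeric matrix.
#' @return A numeric matrix (samples x features).
#' @export
values_of <- function(x) {
  if (inherits(x, c("genotype_matrix", "expression_matrix"))) x$values
  else if (is.matrix(x)) x
  else stop("expected a genotype_matrix, expression_matrix, or numeric matrix")
}

#' Read a genotype or expression matrix from delimited text
#'
#' Files are tab-delimited, UTF-8, with the first row holding feature
#' identifiers (markers or genes) and the first column holding sample
#' identifiers. Missing entries are the literal token `"NA"` or an empty
#' field. Samples are rows, features are columns.
#'
#' @param path Path to the file.
#' @param kind `"genotype"` or `"expression"`.
#' @param missing_token Token treated as missing in addition to empty
#'   fields (default `"NA"`).
#' @return A `genotype_matrix` or `expression_matrix`: a list with
#'   `values` (numeric matrix), `sample_ids`, `marker_ids`/`gene_ids`,
#'   and `missing_mask` (logical matrix).
#' @export
read_matrix <- function(path, kind = c("genotype", "expression"),
                        missing_token = "NA") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(nf) < 2L) stop("parse error: need a header row and at least one sample row in ", path)
  bad <- which(nf != nf[1L])
  if (length(bad) > 0L) {
    stop("parse error: ragged row at line ", bad[1L], " of ", path,
         " (", nf[bad[1L]], " fields, expected ", nf[1L], ")")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  sample_ids <- df[[1L]]
  feature_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("validation error: duplicate sample id '",
         sample_ids[duplicated(sample_ids)][1L], "' in ", path)
  }
  if (anyDuplicated(feature_ids)) {
    stop("validation error: duplicate feature id '",
         feature_ids[duplicated(feature_ids)][1L], "' in ", path)
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[raw == missing_token | raw == ""] <- NA_character_
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  nonnum <- !is.na(raw) & is.na(values)
  if (any(nonnum)) {
    ij <- which(nonnum, arr.ind = TRUE)[1L, ]
    stop("parse error: non-numeric value '", raw[nonnum][1L],
         "' at line ", ij[1L] + 1L, " of ", path)
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  .new_typed_matrix(values, kind)
}

#' Write a matrix in the same delimited dialect `read_matrix` reads
#'
#' Tab-delimited, header row of feature identifiers, first column of sample
#' identifiers, missing values written as `"NA"`. Numbers are written with
#' 17 significant digits so a write-then-read round trip is exact.
#'
#' @param x A `genotype_matrix`, `expression_matrix`, or numeric matrix
#'   with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  values <- values_of(x)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("write_matrix: matrix must have sample and feature identifiers")
  }
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(values)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], fmt(values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Drop genes with any missing expression value
#'
#' Removes every gene column that contains at least one missing entry; the
#' sample set and the order of surviving genes are unchanged. This mirrors
#' the standard pre-processing of array expression panels where genes with
#' any `NA` quantification are excluded outright rather than imputed.
#'
#' @param expr An `expression_matrix`.
#' @return An `expression_matrix` with complete gene columns only.
#' @export
drop_na_genes <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  keep <- colSums(expr$missing_mask) == 0L
  if (!any(keep)) stop("drop_na_genes: all genes contain missing values")
  .new_typed_matrix(expr$values[, keep, drop = FALSE], "expression")
}

#' Mean-impute and min-max scale a genotype matrix
#'
#' Each missing genotype is replaced by its marker's column mean over the
#' non-missing entries; each marker column is then affinely rescaled onto
#' \[0, 1\]. Constant columns map to 0 (they are kept, not dropped, so
#' marker indices stay aligned with the input file). Idempotent.
#'
#' @param geno A `genotype_matrix`.
#' @return A `genotype_matrix` with no missing entries and values in
#'   \[0, 1\].
#' @export
impute_and_scale <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  v <- geno$values
  all_missing <- colSums(!is.na(v)) == 0L
  if (any(all_missing)) {
    stop("impute_and_scale: marker '", colnames(v)[all_missing][1L],
         "' has no observed genotypes")
  }
  mu <- colMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx) > 0L) v[idx] <- mu[idx[, 2L]]
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant columns: (v - lo)/1 = 0
  v <- sweep(sweep(v, 2L, lo, "-"), 2L, rng, "/")
  .new_typed_matrix(v, "genotype")
}

#' Split samples into train / validation / test index sets
#'
#' Deterministic three-way partition of `1:n_samples`. The split is made on
#' a seeded random permutation; set sizes deviate from `n * fraction` by
#' less than one sample. The test set is reserved for final evaluation and
#' is never touched during training or model selection.
#'
#' @param n_samples Number of samples (>= 3).
#' @param fractions Length-3 positive numeric `(train, validation, test)`
#'   summing to 1. Default `c(0.6, 0.2, 0.2)`.
#' @param seed Integer seed.
#' @return An object of class `dataset_split`: a list with `train_idx`,
#'   `validation_idx`, `test_idx`, `seed`.
#' @export
#' @examples
#' split_samples(10, c(0.6, 0.2, 0.2), seed = 1)
split_samples <- function(n_samples, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("split_samples: fractions must be 3 positive numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("split_samples: fractions must sum to 1")
  if (n_samples < 3L) stop("split_samples: need at least 3 samples")
  sizes <- floor(n_samples * fractions)
  if (any((n_samples * fractions) < 1)) {
    stop("split_samples: a split would receive no samples")
  }
  sizes <- pmax(sizes, 1L)
  rem <- n_samples - sum(sizes)
  if (rem > 0L) {
    frac_part <- n_samples * fractions - floor(n_samples * fractions)
    for (k in order(frac_part, decreasing = TRUE)[seq_len(rem)]) {
      sizes[k] <- sizes[k] + 1L
    }
  }
  set.seed(seed)
  perm <- sample.int(n_samples)
  structure(list(
    train_idx      = sort(perm[seq_len(sizes[1L])]),
    validation_idx = sort(perm[sizes[1L] + seq_len(sizes[2L])]),
    test_idx       = sort(perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]),
    seed           = seed
  ), class = "dataset_split")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$values), "samples x", ncol(x$values), "markers;",
      sum(x$missing_mask), "missing entries\n")
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "samples x", ncol(x$values), "genes;",
      sum(x$missing_mask), "missing entries\n")
  invisible(x)
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("Sample split (seed ", x$seed, "): train ", length(x$train_idx),
      ", validation ", length(x$validation_idx),
      ", test ", length(x$test_idx), "\n", sep = "")
  invisible(x)
}
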