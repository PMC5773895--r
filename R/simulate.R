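#' Specification of a simulated two-parent cross
#'
#' Describes a panel of haploid segregants from a cross of two inbred
#' strains: each marker carries one of the two parental alleles (coded
#' 0/1, no heterozygotes), alleles along a chromosome follow a two-state
#' Markov chain with per-adjacent-marker recombination probability `r`,
#' and expression is generated from a sparse set of causal markers per
#' gene plus Gaussian noise, with an optional pairwise-interaction
#' (epistasis) term for a fraction of genes. Missingness can be injected
#' into both matrices to exercise the preprocessing path.
#'
#' @param n_samples Number of segregants.
#' @param n_markers Total marker count, spread near-evenly over
#'   `n_chromosomes`.
#' @param n_chromosomes Number of chromosomes (default 16, the yeast
#'   karyotype).
#' @param recomb_prob Per-adjacent-marker recombination probability in
#'   \[0, 0.5\] (default 0.1).
#' @param n_genes Number of genes.
#' @param causal_per_gene Causal markers per gene (<= `n_markers`).
#' @param effect_dist `"fixed"` (every causal effect = `effect_size`) or
#'   `"normal"` (effects ~ Normal(0, `effect_sd`^2)).
#' @param effect_size Effect magnitude under `"fixed"` (default 1).
#' @param effect_sd Effect standard deviation under `"normal"` (default 1).
#' @param noise_sd Expression noise standard deviation sigma (default
#'   0.3); sigma^2 is the irreducible held-out MSE floor.
#' @param nonlinear_fraction Fraction of genes that additionally carry a
#'   product term over one pair of their causal markers (default 0.2, so
#'   model comparisons see some epistatic signal).
#' @param interaction_effect Coefficient of the product term (default 1).
#' @param missing_rate_geno Fraction of genotype entries set missing
#'   (default 0).
#' @param na_gene_fraction Fraction of genes contaminated with >= 1
#'   missing expression value (default 0); the count of contaminated
#'   genes is exactly `round(na_gene_fraction * n_genes)`.
#' @param seed Integer seed; everything downstream is deterministic
#'   given it.
#' @return A validated list of class `cross_sim_spec`.
#' @export
cross_sim_spec <- function(n_samples, n_markers, n_chromosomes = 16L,
                           recomb_prob = 0.1, n_genes,
                           causal_per_gene = 5L,
                           effect_dist = c("fixed", "normal"),
                           effect_size = 1, effect_sd = 1,
                           noise_sd = 0.3, nonlinear_fraction = 0.2,
                           interaction_effect = 1,
                           missing_rate_geno = 0, na_gene_fraction = 0,
                           seed = 1L) {
  effect_dist <- match.arg(effect_dist)
  if (recomb_prob < 0 || recomb_prob > 0.5) stop("recomb_prob must lie in [0, 0.5]")
  if (causal_per_gene > n_markers) stop("causal_per_gene exceeds n_markers")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  rates <- c(nonlinear_fraction, missing_rate_geno, na_gene_fraction)
  if (any(rates < 0 | rates > 1)) stop("fractions/rates must lie in [0, 1]")
  if (n_chromosomes < 1L || n_chromosomes > n_markers) {
    stop("n_chromosomes must lie in [1, n_markers]")
  }
  structure(list(
    n_samples = n_samples, n_markers = n_markers,
    n_chromosomes = n_chromosomes, recomb_prob = recomb_prob,
    n_genes = n_genes, causal_per_gene = causal_per_gene,
    effect_dist = effect_dist, effect_size = effect_size,
    effect_sd = effect_sd, noise_sd = noise_sd,
    nonlinear_fraction = nonlinear_fraction,
    interaction_effect = interaction_effect,
    missing_rate_geno = missing_rate_geno,
    na_gene_fraction = na_gene_fraction, seed = seed
  ), class = "cross_sim_spec")
}

#' @keywords internal
.chrom_sizes <- function(n_markers, n_chromosomes) {
  sizes <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Simulate segregant genotypes
#'
#' Per sample and chromosome, the first marker's parental origin is
#' Bernoulli(0.5) and each subsequent marker switches origin with
#' probability `recomb_prob`, giving binary genotypes with linkage decay
#' along the chromosome and a forced 0.5 marginal allele frequency.
#' Missing entries are then injected at `missing_rate_geno` (skipped when
#' `inject_missing = FALSE`, e.g. to generate expression from the
#' complete matrix first).
#'
#' @param spec A `cross_sim_spec`.
#' @param inject_missing Inject genotype missingness per the spec
#'   (default `TRUE`).
#' @return A `genotype_matrix` with 0/1 (possibly `NA`) values.
#' @export
simulate_genotypes <- function(spec, inject_missing = TRUE) {
  stopifnot(inherits(spec, "cross_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  sizes <- .chrom_sizes(spec$n_markers, spec$n_chromosomes)
  blocks <- lapply(sizes, function(m) {
    G <- matrix(0L, n, m)
    G[, 1L] <- stats::rbinom(n, 1L, 0.5)
    if (m > 1L) {
      flips <- matrix(stats::runif(n * (m - 1L)) < spec$recomb_prob, n, m - 1L)
      for (j in 2L:m) G[, j] <- ifelse(flips[, j - 1L], 1L - G[, j - 1L], G[, j - 1L])
    }
    G
  })
  values <- do.call(cbind, blocks) * 1.0
  dimnames(values) <- list(sprintf("sample_%03d", seq_len(n)),
                           sprintf("marker_%04d", seq_len(spec$n_markers)))
  if (inject_missing && spec$missing_rate_geno > 0) {
    set.seed(spec$seed + 2L)
    miss <- stats::runif(length(values)) < spec$missing_rate_geno
    values[miss] <- NA_real_
  }
  .new_typed_matrix(values, "genotype")
}

#' Simulate expression from genotypes with known ground truth
#'
#' For each gene, `causal_per_gene` markers are drawn without replacement
#' and the gene's expression is their effect-weighted sum, plus (for the
#' `nonlinear_fraction` of genes) a product term over one pair of its
#' causal markers, plus Normal(0, `noise_sd`^2) noise. A
#' `na_gene_fraction` of genes is then contaminated with 1-3 missing
#' entries each.
#'
#' @param geno A complete `genotype_matrix` (simulate before missingness
#'   injection, or impute first).
#' @param spec The `cross_sim_spec` used to generate `geno`.
#' @return A list with `expression` (an `expression_matrix`) and `truth`
#'   (a `ground_truth`: per-gene causal markers, effects, interaction
#'   pairs, the noise sd and generator seed).
#' @export
simulate_expression <- function(geno, spec) {
  stopifnot(inherits(spec, "cross_sim_spec"))
  X <- values_of(geno)
  if (anyNA(X)) stop("simulate_expression: genotypes must be complete")
  set.seed(spec$seed + 1L)
  n <- nrow(X)
  G <- spec$n_genes
  n_nl <- round(spec$nonlinear_fraction * G)
  nl_genes <- if (n_nl > 0L) sort(sample.int(G, n_nl)) else integer(0)
  E <- matrix(0, n, G,
              dimnames = list(rownames(X), sprintf("gene_%04d", seq_len(G))))
  causal <- vector("list", G)
  for (g in seq_len(G)) {
    mk <- sort(sample.int(spec$n_markers, spec$causal_per_gene))
    beta <- if (spec$effect_dist == "fixed") {
      rep(spec$effect_size, spec$causal_per_gene)
    } else {
      stats::rnorm(spec$causal_per_gene, 0, spec$effect_sd)
    }
    y <- drop(X[, mk, drop = FALSE] %*% beta)
    pair <- NULL
    if (g %in% nl_genes && spec$causal_per_gene >= 2L) {
      pair <- sort(sample(mk, 2L))
      y <- y + spec$interaction_effect * X[, pair[1L]] * X[, pair[2L]]
    }
    if (spec$noise_sd > 0) y <- y + stats::rnorm(n, 0, spec$noise_sd)
    E[, g] <- y
    causal[[g]] <- list(markers = mk, effects = beta, interaction_pair = pair)
  }
  if (spec$na_gene_fraction > 0) {
    set.seed(spec$seed + 3L)
    n_na <- round(spec$na_gene_fraction * G)
    na_genes <- sort(sample.int(G, n_na))
    for (g in na_genes) {
      k <- sample.int(3L, 1L)
      E[sample.int(n, k), g] <- NA_real_
    }
  }
  names(causal) <- colnames(E)
  truth <- structure(list(causal = causal, noise_sd = spec$noise_sd,
                          interaction_effect = spec$interaction_effect,
                          seed = spec$seed),
                     class = "ground_truth")
  list(expression = .new_typed_matrix(E, "expression"), truth = truth)
}

#' Causal-marker index matrix of a ground truth
#'
#' @param truth A `ground_truth`.
#' @return Integer matrix, one row per gene, of causal marker indices.
#' @export
causal_markers <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  t(vapply(truth$causal, function(cg) cg$markers,
           integer(length(truth$causal[[1L]]$markers))))
}

#' Built-in fixture presets
#'
#' `tiny` is a 60-sample, 120-marker, 30-gene panel that trains in
#' seconds; `yeast_scale` mirrors the dimensions of the classic yeast
#' segregant panel: 112 samples, 2956 markers on 16 chromosomes, 7085
#' genes with missingness contaminating exactly 474 genes, so that
#' NA-gene removal leaves 6611 complete genes.
#'
#' @param name `"tiny"` or `"yeast_scale"`.
#' @param seed Integer seed.
#' @return A `cross_sim_spec`.
#' @export
fixture_spec <- function(name = c("tiny", "yeast_scale"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    tiny = cross_sim_spec(
      n_samples = 60, n_markers = 120, n_chromosomes = 4,
      recomb_prob = 0.1, n_genes = 30, causal_per_gene = 5,
      effect_dist = "fixed", effect_size = 1, noise_sd = 0.3,
      nonlinear_fraction = 0.2, interaction_effect = 1,
      missing_rate_geno = 0.02, na_gene_fraction = 0.1, seed = seed),
    yeast_scale = cross_sim_spec(
      n_samples = 112, n_markers = 2956, n_chromosomes = 16,
      recomb_prob = 0.05, n_genes = 7085, causal_per_gene = 5,
      effect_dist = "fixed", effect_size = 1, noise_sd = 0.3,
      nonlinear_fraction = 0.2, interaction_effect = 1,
      missing_rate_geno = 0.01, na_gene_fraction = 474 / 7085, seed = seed)
  )
}

#' Write a named fixture dataset to disk
#'
#' Generates genotypes, expression and ground truth for a preset (or a
#' custom `cross_sim_spec`), and writes `genotype.tsv`, `expression.tsv`
#' (both in the [read_matrix()] dialect) and `truth.json` into `dir`.
#' Expression is generated from the complete genotype matrix; genotype
#' missingness is injected afterwards. Byte-identical across runs with
#' the same seed.
#'
#' @param name Preset name (`"tiny"`, `"yeast_scale"`) or a
#'   `cross_sim_spec`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (ignored when `name` is a spec).
#' @return Invisibly, a list with the three file paths, the spec, and the
#'   `ground_truth`.
#' @export
make_fixture <- function(name = "tiny", dir, seed = 1L) {
  spec <- if (inherits(name, "cross_sim_spec")) name else fixture_spec(name, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno_complete <- simulate_genotypes(spec, inject_missing = FALSE)
  sim <- simulate_expression(geno_complete, spec)
  geno <- geno_complete
  if (spec$missing_rate_geno > 0) {
    set.seed(spec$seed + 2L)
    v <- geno$values
    miss <- stats::runif(length(v)) < spec$missing_rate_geno
    v[miss] <- NA_real_
    geno <- .new_typed_matrix(v, "genotype")
  }
  paths <- list(genotype = file.path(dir, "genotype.tsv"),
                expression = file.path(dir, "expression.tsv"),
                truth = file.path(dir, "truth.json"))
  write_matrix(geno, paths$genotype)
  write_matrix(sim$expression, paths$expression)
  truth_json <- list(
    noise_sd = sim$truth$noise_sd,
    interaction_effect = sim$truth$interaction_effect,
    seed = sim$truth$seed,
    spec = unclass(spec),
    causal = lapply(sim$truth$causal, function(cg) list(
      markers = cg$markers, effects = cg$effects,
      interaction_pair = cg$interaction_pair))
  )
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(paths = paths, spec = spec, truth = sim$truth))
}
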