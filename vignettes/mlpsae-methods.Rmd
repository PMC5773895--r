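---
title: "Predicting gene expression from genotypes with stacked denoising auto-encoders"
author: "mlpsae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene expression from genotypes with stacked denoising auto-encoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a segregant panel — haploid offspring of a cross between two inbred
yeast strains — every individual carries one of the two parental alleles
at each of a few thousand genotyped markers, and the expression of
thousands of genes is measured in the same individuals. Expression is a
quantitative molecular trait shaped in part by those genotypes (the eQTL
signal). `mlpsae` builds *predictive* models of this relationship: given
only the marker genotypes of a sample, predict its full expression
profile. This differs from eQTL mapping, which tests marker–gene pairs
for association but does not predict expression levels.

The data regime is hostile: many more features (markers) and outputs
(genes) than samples, and a low signal-to-noise ratio in which most
markers are irrelevant to most genes. The package therefore ships three
model families behind one fit/predict contract — a sparse linear baseline
(Lasso), an ensemble baseline (Random Forests), and the core deep model —
together with the evaluation protocol needed to compare them honestly.

## The model

The core model (`mlp_sae()`) is a four-layer feedforward regressor:

* **Input layer** — marker genotypes, mean-imputed and min-max scaled to
  $[0, 1]$ (`impute_and_scale()`).
* **Two hidden layers** — each pretrained unsupervised as a *denoising
  auto-encoder*: the layer's input is corrupted by masking a fraction
  $q$ of coordinates to zero, mapped to a code
  $Y = s(XW_{enc} + b_{enc})$, decoded back to a reconstruction $Z$, and
  trained by stochastic gradient descent to minimize the reconstruction
  loss against the *clean* input. Squared error
  $\lVert X - Z\rVert^2$ serves real-valued inputs; binary cross-entropy
  $-\sum_k [x_k \log z_k + (1-x_k)\log(1-z_k)]$ serves binary inputs
  such as the genotypes themselves.
* **Output layer** — a linear multi-output regression head
  $f(x) = \omega^\top h(x) + b$ predicting all genes jointly from the
  top code.

After greedy layer-wise pretraining, the decoders are discarded, the
encoders are stacked (`stack_regressor()`), and the whole network is
fine-tuned end-to-end by backpropagation on the mean squared prediction
error, averaged over batch samples and genes (`finetune()`). An optional
dropout variant retains each input unit with probability $p_{in}$ and
each hidden unit with probability $p_h$ during training and uses
mean-network inference (weights scaled by their feeding units' retention
probability) at prediction time.

```{r fit-sketch}
library(mlpsae)
geno <- impute_and_scale(read_matrix("genotype.tsv", "genotype"))
expr <- drop_na_genes(read_matrix("expression.tsv", "expression"))
fit <- mlp_sae(geno, expr, hidden = c(500, 100), learning_rate = 0.1,
               dropout = dropout_spec(0.5, 0.9), seed = 1)
predict(fit, geno)
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `hidden` | `c(500, 100)` | hidden-layer widths (units); sized for a ~3000-marker panel, scale down for smaller marker sets |
| `q` | 0.2 | corruption level: fraction of input coordinates masked during pretraining |
| `activation` | `"logistic"` | hidden nonlinearity; `"logistic"` matches $[0,1]$-scaled inputs, `"tanh"` suits $[-1,1]$ data |
| `dae_loss` | `"squared_error"` | pretraining reconstruction loss; `"cross_entropy"` is the natural choice for binary genotypes |
| `learning_rate` | 0.1 | SGD step size for fine-tuning; the model-selection grid is $\{0.1, 0.01, 10^{-3}, 10^{-4}, 10^{-5}\}$ |
| `momentum` | 0 | classical momentum; plain SGD by default |
| `batch_size` | 10 | mini-batch size, suited to panels of ~100 samples |
| `epochs` / `patience` | 500 / 25 | fine-tuning cap and early-stopping patience on validation MSE |
| `p_hidden`, `p_input` | 0.5, 0.9 | dropout retention probabilities (hidden units near 0.5, input units near 1) |

Every report produced by the pipeline echoes the complete configuration,
defaults included, so no setting is silent.

## Evaluation protocol

Samples are split 60/20/20 into train/validation/test
(`split_samples()`); the spec of the split and every seed are recorded.
The three-way split resolves an ambiguity in how a separate validation
set relates to cross-validation folds: here, hyperparameters (Lasso
penalty $\alpha$, forest size, MLP learning rate) are chosen by 5-fold
CV *within the training set* (`cv_select()`, grand-mean MSE over genes,
ties broken toward the smaller candidate so selection is
grid-order-invariant), the validation set serves only early stopping of
the network, and the test set is scored once. Reported quantities are
the test MSE, the per-gene squared Pearson correlation between true and
predicted expression (`per_gene_r2()` — affine-invariant, so it measures
tracking of expression changes rather than absolute agreement), and
counts of genes in the standard $R^2$ bins starting at $(0, 0.05]$
(`bin_r2()`). Genes whose $R^2$ is undefined (zero variance) or not
above zero go to an explicit reconciliation bucket so the bin counts
always total the gene count.

## The synthetic cross generator

`cross_sim_spec()` + `simulate_genotypes()` + `simulate_expression()`
emulate a two-parent haploid cross: binary marker alleles (no
heterozygotes), a Bernoulli(0.5) parental origin at the first marker of
each of 16 chromosomes, and a two-state Markov chain that switches
parental origin between adjacent markers with recombination probability
$r$ (default 0.1) — producing the linkage-decay correlation structure a
real panel has. Expression is a sparse linear combination of
`causal_per_gene` markers (fixed effect size 1 by default, the
large-effect regime typical of yeast eQTL) plus Gaussian noise with
standard deviation $\sigma$ (default 0.3); a fraction of genes (default
0.2) additionally carries a product term over one causal-marker pair so
that model comparisons see an epistatic signal the linear baselines
cannot capture. Missingness can be injected into both matrices; the
`yeast_scale` preset contaminates exactly 474 of 7085 genes so NA-gene
filtering leaves 6611, mirroring the classic panel's dimensions
(112 samples, 2956 markers).

What the generator does *not* emulate: genetic maps in centimorgans
(marker spacing is implicitly uniform), mutation or multi-generation
pedigrees, expression heteroscedasticity, batch effects, and correlated
residuals between co-regulated genes. Tests passing on this generator
therefore demonstrate correctness of the machinery and recoverability of
sparse additive signal under clean conditions — not performance on real
expression arrays.

## Numerical choices

* The squared-error reconstruction loss is a per-sample *sum* over
  coordinates; batch objectives average per-sample losses. The binary
  reconstruction objective is the standard cross-entropy (any sign
  variant that subtracts the $(1-x)\log(1-z)$ term inside the bracket is
  unbounded below and cannot be a loss), with predictions clipped to
  $[10^{-12}, 1 - 10^{-12}]$ to keep logarithms finite.
* Weights initialize uniformly on $[-r, r]$,
  $r = \sqrt{6/(fan_{in}+fan_{out})}$, scaled by 4 for logistic units;
  biases start at zero; every draw is seeded, and a fit is bitwise
  reproducible given its seed.
* Corruption masks with $q \in \{0, 1\}$ and dropout with $p = 1$
  consume no random numbers, so a dropout model at full retention is
  bitwise identical in trajectory to the plain model — a property the
  test suite asserts.
* Mean-imputed genotype columns are min-max scaled; constant columns map
  to 0 and are kept so marker indices stay aligned with input files.
  Preprocessing is idempotent.
* Lasso problems ($\tfrac{1}{2n}\lVert Xw - y\rVert_2^2 +
  \alpha\lVert w\rVert_1$, unpenalized intercept, one problem per gene)
  are solved by glmnet's coordinate descent without predictor
  standardization; the objective evaluator and a null-threshold check
  live in the package, and the test suite verifies fits against an
  independent coordinate-descent solver to $10^{-6}$.
* Grand-mean MSE (over all genes and samples jointly) is the
  model-selection scalar; CV candidates whose training diverges score
  infinity and drop out of the argmin.

## Open design points and how they were resolved

* **Per-gene vs multi-task Lasso** — per gene, the direct reading of the
  single-response objective; multi-task penalties are out of scope.
* **Joint vs per-gene output head** — one linear head predicting all
  genes jointly; a per-gene deep model would be computationally
  intractable at thousands of genes and the shared hidden layers are
  the point of the architecture.
* **Dropout averaging** — weight scaling at inference (exact for linear
  layers; the standard approximation otherwise), verified against a
  20000-pass Monte-Carlo average on a linear network.
* **Pretraining vs fine-tuning rates** — independent settings sharing
  the same default grid.
* **Tie-breaking in model selection** — smaller penalty / fewer trees /
  smaller learning rate, so re-ordering the grid cannot change the
  selection.

## Problem sizes used by the shipped checks

The test suite trains on small instances chosen to finish quickly while
still exercising every code path: gradient checks on networks of ~50
parameters; pretraining fixtures of 50–200 samples; and a recovery study
of 500 simulated segregants with 100 markers and 20 genes (10 causal
markers each, $\sigma = 0.3$), split 380/60/60, with the learning rate
cross-validated over the default grid. The acceptance script re-runs
that study end to end and additionally generates the `yeast_scale`
fixture to verify the 112 × 2956 × 7085 → 6611 structural dimensions.

## Known limitations

* With a few hundred training samples, the fine-tuned network's held-out
  MSE remains a multiple of the irreducible noise floor $\sigma^2$ on
  the recovery study above — the shipped checks compute the ratio
  directly — whereas the sparse linear baseline sits much closer to the
  floor and recovers essentially all causal markers at the
  least-shrinkage grid penalty. Deep models in this regime trade
  statistical efficiency for the capacity to represent non-additive
  signal; on purely additive simulated data that trade buys nothing.
* Default logistic pretraining with the squared-error loss can saturate
  hidden codes on binary genotype inputs; the cross-entropy
  reconstruction loss (or tanh units) preserves more linearly decodable
  structure and is the recommended setting for genotype data.
* Optimization is plain (optionally momentum-accelerated) SGD; there is
  no adaptive-step optimizer, so learning-rate choice matters and is
  deliberately part of the cross-validated grid.
* The model uses no genomic positions, annotations, or
  epigenetic features; markers are exchangeable columns.
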