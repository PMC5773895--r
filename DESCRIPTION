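Package: mlpsae
Title: Gene Expression Prediction from SNP Genotypes with Stacked
    Denoising Auto-Encoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gene-expression quantifications from SNP genotypes with
    a multilayer perceptron whose hidden layers are pretrained as stacked
    denoising auto-encoders and whose output layer is a linear multi-output
    regression head, optionally regularized by dropout. Includes Lasso and
    Random-Forests baselines behind a common fit/predict contract, k-fold
    cross-validated hyperparameter selection, per-gene R-squared reporting
    with binning, a simulator of two-parent yeast-cross genotype/expression
    panels with known ground truth, and a command-line pipeline
    (simulate/train/predict/evaluate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    graphics,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
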