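Package: spcabench
Title: Sparse Principal Component Analysis Estimators and Simulation Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements six sparse principal component analysis estimators --
    simple-structure rotation (Varimax, Simplimax) followed by thresholding,
    regularized rank-one singular value decomposition with deflation
    (sPCA-rSVD), elastic-net sparse PCA (SPCA), greedy cardinality-penalized
    sparse PCA (pathSPCA), and the generalized power method with a lasso
    penalty (GPower) -- together with synthetic data generators that plant
    sparse component loadings and/or weights at a controlled proportion of
    explained variance, performance measures (squared relative error,
    misidentification rate, explained variance, Tucker congruence, index of
    sparseness), exhaustive component alignment over permutations and signs,
    and a crossed-design simulation runner for comparing the estimators under
    matching, double, and mismatching sparsity regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    glmnet
Suggests: testthat (>= 3.0.0), jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
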