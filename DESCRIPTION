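Package: walkback
Title: Walk-Back Signature Removal and Region Classification for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for recovering faint regional (spatial) identity from
    multi-dataset single-cell RNA-seq data in which dominant functional-state
    gene programs mask it.  Implements per-cell quality control (complexity
    filtering, mitochondrial mixture-model filtering, simulated-doublet
    scoring), marker-panel cell selection, analytic Pearson-residual
    normalization and highly variable gene selection, pairwise soft-k-means
    batch integration with linear correction, robust rank aggregation of
    anchor-gene rankings into a shared functional-state signature, signature
    subtraction with correlated-gene removal, mutual-kNN/MST path-connectivity
    graphs with fuzzy simplicial weighting, constant Potts model Leiden
    microclustering, two-stage feature selection with an RBF support vector
    machine region classifier under grouped cross-validation, evaluation
    statistics (multiclass Matthews correlation, corrected resampled t-test,
    Bayesian model comparison, hurdle differential expression), and a
    negative-binomial synthetic-data generator with planted regional and
    state programs so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    e1071,
    glmnet,
    xgboost,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
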