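Package: crcgene
Title: Collaborative Representation Classification for Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies high-dimensional gene-expression profiles by coding each
    query sample over the pooled dictionary of all training samples with an
    l2-regularized (ridge) least-squares fit, assigning the class whose coding
    sub-vector yields the smallest regularized reconstruction residual.
    Includes a sparse-representation baseline with an orthogonal matching
    pursuit coder, compressive-sensing dimensionality reduction through very
    sparse random projections with an empirical distortion audit, a two-sample
    t-test / one-way ANOVA gene prefilter, leave-one-out and repeated k-fold
    cross-validation with a reduced-dimension sweep protocol, readers and
    writers for delimited and GCT/CLS expression matrices, and a synthetic
    expression-data generator with controlled class separation and feature
    redundancy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
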