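Package: batchdissect
Title: Missing-Value-Tolerant Batch Effect Correction by Matrix Dissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch effect adjustment for integrated omics expression matrices
    with arbitrary missingness. Features are grouped by the combination of
    batches in which they hold sufficient numerical values, and each resulting
    sub-matrix is adjusted independently with a missing-value-aware ComBat-style
    empirical Bayes kernel or a limma-style linear-model kernel. Includes batch
    blocking with optional sparsity, Jaccard and seriation orderings to shrink
    the dissection, rescue of features with unique batch combinations by minimal
    cropping, quality-control metrics (missing-value-tolerant Euclidean
    distances, silhouette widths, k-nearest-neighbour misclassification,
    per-feature coefficients of variation), and a synthetic multi-batch data
    generator with missing-not-at-random censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel,
    cluster,
    optparse
Suggests:
    testthat (>= 3.0.0),
    sva,
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
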