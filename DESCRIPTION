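Package: edyloy
Title: Detection of Y-Chromosome Loss and Extreme Downregulation of
    Y-Linked Gene Expression in Bulk, Single-Cell and Copy-Number Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects extreme downregulation of Y-chromosome gene
    expression (EDY) in bulk and single-cell transcriptomes and loss of
    the Y chromosome (LOY) in segmented copy-number data, and associates
    these calls with malignant-progression outcomes. Implements
    single-sample gene-set variation scoring (kernel-smoothed expression
    CDF, symmetric rank statistic and weighted Kolmogorov-Smirnov random
    walk), reference-calibrated EDY thresholds, a zero-UMI single-cell
    EDY classifier with QC and binned-control module scores, a
    cellularity- and ploidy-adjusted Y-chromosome copy-number signal,
    exact 2x2 inference (Fisher test, Woolf and conditional-exact odds
    ratio intervals), the Jonckheere-Terpstra ordered trend test,
    permutation association tests, pathway activity scoring by
    multivariate linear models, and seeded synthetic-data generators for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
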