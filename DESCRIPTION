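Package: nestvar
Title: Variance Decomposition and Coexpression Analysis for Replicated
    Expression Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions per-gene transcript variance from nested expression
    designs (replicate samples within animals, animals within cages) into
    within-animal, between-animal, and between-cage components; identifies
    variable genes with a pooled-variance-scaled chi-squared test and a
    shrunken F statistic with permutation p-values; detects coexpression
    modules among variable genes via squared-correlation adjacency and
    topological overlap; characterizes modules by eigengenes, intraclass
    correlation and between-/within-animal profile correlations; and tests
    modules for gene-set enrichment and cross-tissue overlap. Includes a
    simulator for replicated array studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    lme4,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
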