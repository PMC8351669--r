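Package: agingnet
Title: Segmented Regression and Co-Expression Network Analysis of Aging
    Time-Course Transcriptomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates per-gene segmented (piecewise-linear) regression over
    an aging time course with weighted gene co-expression network analysis to
    call high-confidence age- and sex-associated gene signatures in bulk
    RNA-seq count data. Provides quality control and normalization (library
    depth filtering, sample-network outlier removal, median-of-ratios size
    factors, a closed-form negative-binomial variance-stabilizing transform,
    PCA), exhaustive BIC-selected breakpoint models with a
    permutation-calibrated adjusted R-squared cutoff, biweight
    midcorrelation networks with topological overlap, module eigengenes and
    module-trait statistics, hub gene calling, hypergeometric gene-set
    over-representation analysis, Markov clustering of term-similarity
    graphs with automatic cluster labelling, and a negative-binomial
    time-course simulator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2
Config/testthat/edition: 3
biocViews: Transcriptomics, TimeCourse, Network, GeneExpression,
    Regression, NetworkEnrichment
RoxygenNote: 7.3.3
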