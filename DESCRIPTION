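Package: mtrtools
Title: Regional Missense Constraint and Gene-Customized Variant Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Missense Tolerance Ratio (MTR), a sliding-window,
    sequence-context-normalized measure of regional depletion of missense
    variation in protein-coding genes, from population standing-variation
    data. Supplements each window with a binomial exact test against
    neutrality and Benjamini-Hochberg false-discovery-rate control, and
    derives gene-specific percentile thresholds of missense depletion.
    Provides the surrounding gene-customized interpretation workflow:
    stratification of population control variants into mutually exclusive
    frequency-defined groups, qualification of pathogenic-reported variants
    by de novo and segregation evidence, enrichment statistics (quartile
    binomial, rank and presence tests), shadow-feature random-forest
    importance screening, and AIC-guided stepwise logistic models yielding a
    gene-specific probability of pathogenicity (GPP) score. Includes a
    synthetic-data generator producing transcripts, standing variation with
    planted regional depletion, pathogenic variant sets and feature matrices
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    randomForest,
    caret,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
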