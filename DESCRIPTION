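Package: dapsize
Title: Differential Protein Abundance and Empirical-Null Effect Size for
    DIA Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-search quantitative analysis of data-independent
    acquisition (DIA) proteomics experiments with a two-group design, as
    used in aquaculture feeding trials. Reads DIA-NN protein-group
    matrices, performs detection filtering, variance-stabilizing
    normalization, maximum-likelihood (EM) imputation of missing values,
    and empirical-Bayes moderated two-group testing with dual
    p-value/fold-change calling of differentially abundant proteins.
    Quantifies dietary effect size by contrasting within-diet half-split
    comparisons (an empirical null) against between-diet comparisons,
    and summarizes the percentage of the proteome that responds.
    Includes NIPALS PLS-DA with confidence ellipses, parallel reaction
    monitoring (PRM) roll-up and concordance checks, feeding-trial
    production indices (SGR, FCR, relative food intake), and a
    ground-truth synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
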