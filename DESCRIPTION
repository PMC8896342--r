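Package: MODYexpress
Title: Targeted Expression-Panel Normalization and Outlier Analysis for
    Suspected-MODY Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for targeted hybridization-based expression
    panels (NanoString nCounter-style) applied to cohorts of patients with
    clinically suspected maturity-onset diabetes of the young (MODY) and
    healthy controls. Implements RCC sample-file and count-matrix input,
    negative-control background thresholding, positive-control technical
    normalization, geNorm reference-gene selection with content
    normalization, control-referenced z-score outlier calling, clinical
    classification of patient metadata, normality-gated two-group testing
    and correlation analysis, and a seeded synthetic-cohort generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
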