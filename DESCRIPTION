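Package: gravitrans
Title: Differential Expression Analysis for Short-Duration Altered-Gravity
    Transcriptome Experiments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infrastructure for analysing bulk transcriptome responses to
    short episodes of altered gravity (parabolic flight and suborbital
    ballistic rocket experiments). Implements the signed fold-change
    convention with negative reciprocals for ratios below one, per-transcript
    two-sample t-tests and differential-expression calling, construction of
    control-filtered gravisensitive transcript sets with direction-aware
    exclusion rules, attribution of microgravity responses to
    SKF-96365-sensitive cation channels, cross-platform direction-concordance
    analysis, and a four-category time-course adaptation classification.
    Ships a planted-truth simulator of log-normal expression matrices so the
    whole inference chain can be validated against known ground truth, and
    packaged reference tables of published cross-platform fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: GeneExpression, DifferentialExpression, Microarray, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
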