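Package: raterDx
Title: Tie-Aware Evaluation of Probabilistic Multi-Class Diagnostic Raters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation framework for reader studies in which an automated
    classifier and human experts each assign a probability vector over
    several diagnostic categories to every case. Implements a tie-tolerant
    highest-probability decision rule with partial-credit scoring,
    fractional confusion matrices, classification metrics with Wilson
    confidence intervals, tie-aware Cohen's kappa, continuous-score
    agreement statistics (Pearson, Spearman, single-measure
    absolute-agreement ICC, Bland-Altman limits of agreement, Levene's
    test), ROC analysis with stratified bootstrap confidence intervals and
    DeLong's paired test, probability calibration (Brier score, calibration
    curves) and decision curve analysis, a power tool for comparing two
    correlated AUCs, and a latent-severity simulator of complete
    multi-reader studies with known operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    withr
biocViews: Classification, StatisticalMethod, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
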