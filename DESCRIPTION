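Package: mircross
Title: Cross-Kingdom miRNA Target Prediction and Expression Panel Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting targets of diet-derived plant microRNAs in
    animal transcripts and relating the predictions to qPCR expression panels.
    Candidate miRNA-mRNA interactions are scored by an ensemble of duplex
    predictors (seed complementarity and a nearest-neighbour free-energy
    dynamic program, plus an external-predictor plugin contract), aggregated
    into a Fermi-Dirac energy score (ES) and a summed probability score (PS),
    and classified by a calibrated support vector machine with a 60%
    probability cutoff and a cross-species consistency intersection. The
    expression side implements 2^-ddCt relative quantification with
    fold-change significance thresholds (>1.50 / <0.5), panel summaries,
    prediction-expression concordance with a hypergeometric enrichment
    diagnostic, and exact noncentral-t sample-size computation. A synthetic
    data module generates all pipeline inputs with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    e1071,
    pROC,
    jsonlite,
    withr,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
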