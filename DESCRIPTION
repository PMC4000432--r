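Package: clustericc
Title: Intracluster Correlation, Design Effects and Sample-Size Inflation
    for Cluster-Sampled Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-way ANOVA estimation of the intracluster correlation
    coefficient (ICC, Kish's "roh") for unbalanced cluster samples with
    binary or continuous outcomes, asymptotic and F-pivot confidence
    intervals, survey design effects, and design-effect-based sample-size
    inflation for single-stage cluster designs. Ships a machine-readable
    transcription of the published per-variable ICC tables of the Brazilian
    Multicenter Study on Preterm Birth (EMIP; 261 variables over 20 hospital
    clusters) together with batch estimation and summary tools that
    reproduce the study's aggregate statistics, and a synthetic multicenter
    data generator (Gaussian random intercepts, beta-binomial) used to
    validate every estimator by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
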