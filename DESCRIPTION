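Package: prsresponse
Title: Polygenic Risk Score Pipelines for Antipsychotic Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the association between polygenic risk scores and
    response to antipsychotic treatment in naturalistic psychiatric cohorts.
    Provides variant-level genotype quality control (call rate, minor allele
    frequency, Hardy-Weinberg equilibrium) with EIGENSTRAT-style ancestry
    principal components, greedy linkage-disequilibrium clumping, weighted
    allele-count score construction with allele alignment and missing-data
    policies, a rule engine classifying treatment response from longitudinal
    Clinical Global Impressions records and treatment events, covariate-adjusted
    logistic association models, ROC and Youden-index diagnostic evaluation, and
    a seeded synthetic-cohort generator with known ground truth so the full
    pipeline is testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
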