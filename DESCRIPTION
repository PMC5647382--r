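Package: minsig
Title: Minimal DNA Methylation Signatures for Molecular Subgroup Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Derives minimal, multiply-redundant CpG methylation signatures
    from genome-scale beta-value matrices and applies them to degraded,
    single-sample assay data. Implements non-negative matrix factorisation
    (NMF) consensus clustering for molecular subgroup discovery, empirical
    Bayes moderated-t candidate selection, classifier-fusion locus ranking
    under cross-validation, redundancy optimisation by random locus masking,
    confidence-thresholded support vector machine classification with
    expectation-maximisation imputation of missing loci, a sample-level
    quality-control cascade for primer-extension methylation assays, and
    Kaplan-Meier / log-rank survival reporting for the resulting subgroups.
    Ships a synthetic-cohort generator that emulates methylation array
    cohorts with planted subgroup structure, FFPE-grade noise and locus
    dropout, control-DNA mixture series and subgroup-dependent survival, so
    the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    e1071,
    nnet,
    rpart,
    survival,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
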