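Package: ctnorm
Title: Normative Modeling of Longitudinal Cortical Thickness with Scanner
    Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Hierarchical Bayesian normative models of regional cortical
    thickness with age as covariate and scanner/sex batch effects, fitted on
    a multi-site healthy reference cohort and transferred to unseen scanners
    via informed priors. Produces per-scan deviation (z) scores, extreme
    deviation (|z| > 2) case-control statistics, longitudinal linear
    mixed-effects analyses of diagnosis-by-time effects and symptom
    associations with Benjamini-Hochberg FDR control, quality-control
    filtering and attrition-bias diagnostics. Includes a synthetic
    multi-site longitudinal cohort generator so the full pipeline is
    testable without access to clinical MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    rjags,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
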