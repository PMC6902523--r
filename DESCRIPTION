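Package: vitalhf
Title: Representation Learning on Intraoperative Vital Signs for
    Perioperative Heart-Failure Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms intraoperative vital-sign monitoring series (heart
    rate, non-invasive systolic and diastolic blood pressure, SpO2 and the
    derived pulse pressure) into three feature representations for
    perioperative heart-failure risk classification: per-patient statistical
    moment features with a correlation-based filter; a text representation
    built from piecewise aggregate approximation (PAA), symbolic aggregate
    approximation (SAX) and a rule engine, summarised by latent Dirichlet
    allocation (LDA) topic proportions; and a grid-image representation of
    each channel's time-value point counts classified by a compact
    convolutional neural network.  Includes a synthetic-cohort generator with
    a configurable class signature, a suite of eight reference classifiers,
    stratified cross-validation, and ROC/confusion metric reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
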