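Package: adcascade
Title: Causal Simulation of the Alzheimer's Disease Biomarker Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward simulation of the dynamic biomarker cascade in
    Alzheimer's disease as a system of five coupled nonlinear ordinary
    differential equations: amyloid pathology, amyloid-related phospho-tau,
    aging/SNAP-related tau, neurodegeneration, and cognitive impairment.
    Includes the published early-onset and late-onset (amyloid-first,
    tau-first) scenario parameterizations and an anti-amyloid therapy
    scenario driven by a Heaviside step input, least-squares calibration of
    logistic carrying capacities, biomarker onset detection against a
    clinical detection threshold, therapy-effect metrics, and recovery of
    model parameters from noisy synthetic longitudinal observations by
    bounded nonlinear least squares.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
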