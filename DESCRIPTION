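Package: cvwork
Title: Closed-Loop Cardiovascular Modelling and Non-Invasive Myocardial
    Work Estimation in Aortic Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lumped-parameter closed-loop model of the cardiovascular
    system (automata-based cardiac conduction, time-varying elastance
    chambers, dynamic Bernoulli/inertance heart valves, elastance-based
    systemic and pulmonary circulations) with tools for model-based,
    patient-specific estimation of left-ventricular pressure in aortic
    stenosis. Includes pressure-strain myocardial work indices (global
    constructive and wasted work, work efficiency), Morris
    elementary-effects sensitivity screening, two-step evolutionary
    parameter identification with Monte-Carlo cross-validation, and a
    synthetic virtual-patient cohort generator for end-to-end validation
    against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
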