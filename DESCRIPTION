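Package: cscsense
Title: Global Sensitivity and Bifurcation Workflow for Cancer Stem Cell
    Tumor Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase parameter-exploration workflow for ordinary
    differential equation models of hierarchically structured tumors:
    Latin hypercube sampling of parameter space, ensemble simulation,
    time-course partial rank correlation coefficients (PRCC) with
    significance testing, color-coded level-partition visualization, and
    one-parameter bifurcation analysis with transcritical-point
    detection. Ships a five-compartment cancer stem cell population
    model with feedback-limited proliferation (cancer stem cells, two
    progenitor levels, terminal cells, dead cells), its analytic
    Jacobian, and the closed-form tumor invasion boundary, plus fixture
    models for validating the statistical machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
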