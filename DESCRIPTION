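Package: dupasim
Title: Patient-Level Simulation of Anti-TNF Treatment for Early-Stage
    Dupuytren's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Health-economic evaluation of intranodular adalimumab versus
    standard care for progressive early-stage Dupuytren's disease. Implements
    a discrete-time (six-month cycle) patient-level simulation of flexion
    deformity progression, nodule quiescence, late-stage surgical pathways
    and mortality over a lifetime horizon; discounted cost and QALY accrual
    with incremental cost-effectiveness analysis; probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves; expected value of
    perfect and partial perfect information; one-way (tornado) sensitivity
    analysis; and a within-trial bootstrap cost-utility analysis on synthetic
    trial data. All inputs are supplied through editable YAML configuration
    with per-value provenance tags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
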