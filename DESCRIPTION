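Package: dynpet
Title: Quantitative Dynamic FDG-PET Kinetics, Fractal Heterogeneity and
    Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of dynamic 18F-FDG PET/CT
    studies: forward simulation and weighted nonlinear fitting of the
    two-tissue compartment model with derivation of the irreversible
    influx rate Ki = (K1*k3)/(k2+k3), box-counting fractal dimension of
    voxel time-activity curves, 50%-isocontour volume-of-interest
    extraction, standardized uptake value (SUV) quantification with
    hottest-lesion selection and cohort median summaries, Kaplan-Meier /
    log-rank progression-free-survival screening of median-dichotomized
    PET parameters, and a fully seeded synthetic dynamic-PET cohort
    generator so that every pipeline stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
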