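Package: switchsense
Title: Switching-Observer Soft Sensors for Monod Chemostat Bioprocesses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design of data-driven soft sensors for single-input single-output
    nonlinear bioprocesses, worked out in full for the Monod-kinetics
    chemostat. The package simulates the nonlinear chemostat, derives
    state-space and input/output linear approximants at operating points on
    the operating trajectory, quantifies approximant accuracy, identifies
    the I/O coefficients by recursive least squares on Butterworth-filtered
    records, builds full-order Luenberger observers by pole placement with
    convergence and steady-state error metrics and constrained pole
    optimization, and composes a bank of observers with target operating
    areas, a dense-web overlap check, multi-step transition planning and a
    switching supervisor that estimates the unmeasured biomass state from
    dilution-rate and substrate measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
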