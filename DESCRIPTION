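Package: surgekinetics
Title: Population-Kinetics Models of Mass-Casualty Surge Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic compartmental (population-kinetics) models of the
    triage, treatment and discharge of a disaster surge cohort by trauma
    centers operating at finite surge capacity. Provides closed-form piecewise
    solutions for a single adult center, for the two-center case in which a
    pediatric trauma center is also available to the pediatric cohort, and for
    an extension with explicit per-compartment death rates; fits the rate
    constants to observed triage timescales, propagates parameter uncertainty
    through local sensitivity and variance matrices, and runs scale-factor and
    mortality scenario experiments. A fixed-step Runge-Kutta integrator with
    exact regime switching serves as an independent numerical cross-check of
    every closed form.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
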