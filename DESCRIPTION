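Package: tactillusion
Title: Skin Contact Mechanics and Psychophysics of the Elasticity-Curvature Illusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Layered hyperelastic (Neo-Hookean) finite-element modelling of
    fingertip contact with compliant spherical stimuli, and the measurement and
    psychophysical analytics that go with it. Solves axisymmetric and
    plane-strain frictionless contact under force control, extracts cutaneous
    cue profiles (interface stress, strain energy density, surface deflection)
    and proprioceptive force-displacement curves, calibrates layer moduli in
    two steps, quantifies contact area from ink-stamped fingerprint images via
    the shoelace formula, extracts force rates from indentation traces, and
    scores same-different discrimination sessions with d-prime under the
    differencing rule. Includes seeded synthetic-data generators for every
    input so the full pipeline can be exercised without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
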