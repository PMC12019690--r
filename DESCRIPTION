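Package: thermoshift
Title: Species Distribution Models with Simulated Shifts in Upper Thermal Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-only species distribution modelling (a MaxEnt-style
    penalized exponential model with linear, quadratic and product features),
    spatial block cross-validation, and a logistic transformation of the
    temperature layer that simulates a 1-5 degree Celsius increase in a
    species' upper thermal tolerance.  Projections to warming scenarios are
    binarized at an occurrence-capture threshold and summarised as habitat
    lost, habitat recovered per degree of added tolerance, and minimum
    suitable latitude per ocean basin.  A seeded synthetic-world generator
    with a planted thermal niche makes the whole pipeline testable at desk
    scale without external raster downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
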