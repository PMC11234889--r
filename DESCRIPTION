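Package: mlatsim
Title: Micro-Level Activity Time Series Exposure Simulation for
    Children's Dust and Soil Ingestion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven stochastic simulation of young children's dermal
    dust/soil hand loading and non-dietary ingestion from micro-level
    activity time series (MLATS): parsing and validation of videotranslation
    text files, a semi-Markov synthetic activity generator, exposure-factor
    distribution sampling, per-contact dermal transfer and mouthing-removal
    dynamics, dermal and ingestion dose algorithms, Monte Carlo virtual-child
    population runs with convergence diagnostics, and laboratory mass
    quantification (gravimetric difference, Coulter-style volumetric mass
    M = V x rho, pycnometer density, hand-trace area).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
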