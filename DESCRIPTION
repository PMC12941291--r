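Package: migrisk
Title: Finite-Bath Migration Kinetics, Bioaccessibility and Dietary Risk
    of Packaging Additives
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the transfer of additives (organophosphate flame
    retardants and similar migrants) from polymer food-contact films into
    foods as Fickian diffusion into a finite, well-stirred phase, fits
    diffusion and partition coefficients to migration time series,
    computes bioaccessibility from simulated-digestion measurements with
    procedural-blank correction, and combines migration ratio,
    bioaccessibility and consumption into bioaccessibility-adjusted
    estimated daily intakes and hazard quotients. Includes a seeded
    synthetic-data generator for migration curves and digestion
    measurements, a finite-difference reference solver for the diffusion
    model, and a small configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
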