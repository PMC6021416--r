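Package: caprokin
Title: Growth Kinetics and Chain-Elongation Modelling for Anaerobic
    Caproate Producers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for high-throughput kinetic characterisation of
    anaerobic bioproduction strains such as Clostridium kluyveri.
    Extracts specific growth rates from 96-well plate optical-density
    time series by fitting the Richards equation to log-transformed,
    blank-corrected curves; selects and calibrates per-compound kinetic
    rate laws (Monod, Haldane, toxicity-limit and linear product
    inhibition) into a combined multiplicative growth model with
    Fisher-information confidence intervals; and drives a two-reaction
    dynamic mass-balance model of ethanol/acetate chain elongation to
    butyrate and hexanoate. Includes a synthetic-data generator for the
    full experimental design space so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
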