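Package: fibresim
Title: Mechanically Gated Simulation of Fibre Attrition During Enzymatic
    Hydrolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of plant-fibre length attrition during
    mixed enzymatic hydrolysis of lignocellulosic biomass. Fibres are
    modelled as simply supported beams; the closed-form bending-moment
    envelope defines a probable failure region (PFR) in the middle of each
    fibre, and breakage occurs only when a uniformly drawn load point falls
    inside it. A step-wise weakening schedule for the strength-to-force
    ratio M_u/P emulates progressive enzymatic weakening, reproducing the
    stagnation of fibre-length distributions observed late in hydrolysis.
    Includes a random-segmentation null model, a synthetic initial-population
    generator, length-weighted binning into the standard length classes,
    total-variation comparison of binned distributions, stagnation detection
    and grid-search calibration of the weakening schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
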