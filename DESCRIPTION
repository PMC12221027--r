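Package: paleosuit
Title: Paleoclimate-Driven Crop Cultivation Suitability Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for agroclimatic suitability analysis under
    simulated past climates. Downscales coarse-grid monthly climate snapshots
    onto a fine reference climatology with the additive delta method, scores
    crop-specific cultivation suitability with a fuzzy law-of-the-minimum
    niche model over climatic, topographic and soil parameters, aggregates
    crops into a hybrid rotation-suitability model with areal class
    statistics and coefficient-of-variation maps, and validates simulated
    climate series against proxy reconstructions by dynamic time warping
    with configurable step patterns. Ships a synthetic-world generator so
    every stage is exercisable and testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ncdf4,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
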