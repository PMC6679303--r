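Package: wheatDA
Title: Ensemble Kalman Filter Assimilation of LAI and Soil Moisture into a
    Water-Limited Wheat Growth Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily-step, water-limited winter wheat growth simulator
    (thermal-time phenology, leaf-cohort canopy dynamics, light-use-efficiency
    assimilation, one-layer soil water bucket) coupled to an ensemble Kalman
    filter with perturbed observations for joint assimilation of leaf area
    index and root-zone soil moisture. Includes a synthetic weather and
    observation generator for twin experiments, four assimilation schemes
    (open-loop, LAI-only, SM-only, joint), regional grid runs with a wheat
    fraction mask, and evaluation statistics (R-squared, mean relative error,
    RMSE) for scheme comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
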