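Package: aqgapfill
Title: Sub-Range Neural Regression for Air-Quality Gap Filling
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Approximates missing hourly air-pollutant concentrations from
    co-measured pollutants and meteorology with ensembles of small multilayer
    perceptrons trained on equal-count concentration sub-ranges. Implements
    two segmentation schemes: RVS (cases sorted and partitioned by the real
    target concentration, an oracle that quantifies the potential gain) and
    PVS (a preliminary full-range model's predictions define the sub-ranges
    and route unseen cases). Includes hourly monitoring-data ingestion and
    complete-case preparation, seeded train/validation/test splitting, BFGS
    training with a fixed epoch cap and best-of-restarts selection, MAE/RMSE
    sub-range error aggregation with percentage-change comparison against the
    full-range model, and a synthetic generator of monitoring-like hourly
    series for testing without access to station data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
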