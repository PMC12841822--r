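Package: climexrf
Title: Mechanistic and Correlative Species Distribution Modelling for a
    Host-Pest System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint species-distribution modelling of a host plant and its
    insect pest. A mechanistic ecoclimatic-index engine (weekly temperature
    and soil-moisture growth indices, annual cold/heat/dry/wet stress
    accumulation) scores host suitability on gridded monthly climate, with
    genetic-algorithm calibration of the physiological parameters against
    occurrence records. A correlative random-forest model on 19 bioclimatic
    predictors, screened by Pearson correlation and LASSO, scores pest
    suitability, which is then restricted to the host's suitable range,
    classified into five levels by Jenks natural breaks, and summarised as
    latitude-weighted habitat areas and per-region changes between climate
    epochs. A seed-deterministic synthetic-world generator supplies climate,
    bioclimatic layers, occurrences and region masks for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    geosphere,
    glmnet,
    randomForest,
    jsonlite
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
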