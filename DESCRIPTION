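Package: amlscape
Title: Scenario-Based Simulation of Abandoned Mine Land Reclamation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coupled non-spatial/spatial modelling of land reclamation on
    abandoned mine land (AML). Provides ordinal mined-land suitability
    assessment by the limit-condition ("cask principle") method, linear
    programming of future land-use demand under land-use-niche and
    ecosystem-service-value objectives, CLUE-S-style iterative spatial
    allocation of yearly demand on a categorical raster driven by binomial
    logit suitability surfaces, landscape-level pattern metrics
    (FRAGSTATS-style), and map-agreement evaluation. A seeded
    synthetic-landscape generator with known logit structure makes the whole
    pipeline testable without proprietary survey rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
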