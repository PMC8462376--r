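Package: mycospat
Title: Spatial Ecology of Paired Soil and Phylloplane Fungal Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired-habitat, spatially explicit fungal
    metabarcoding surveys in which soil and phylloplane (leaf-surface)
    communities are sampled at the same grid locations along transects.
    Provides inter-habitat spatial autocorrelation tests against a
    randomized-pairing null, occurrence-based habitat
    specialist/generalist classification, occupancy summaries and
    occupancy-abundance curves, per-OTU geographic range estimation via
    Mantel screening and exponential semivariogram fitting, ordinary
    kriging of OTU abundance surfaces, and a synthetic-data generator
    that simulates spatially autocorrelated, habitat-coupled OTU tables
    with known ground truth for validating every inference stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
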