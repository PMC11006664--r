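Package: posimap
Title: Satellite Mapping and Multi-Year Monitoring of Posidonia oceanica Meadows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An operational pipeline for mapping the Mediterranean seagrass
    Posidonia oceanica from multi-date shallow-water surface-reflectance
    imagery and bathymetry. Per-year image archives are screened and median
    stacked into clean composites, bathymetry is resampled and used to crop
    beyond the 40 m depth limit, habitat ground truth is rasterized, and a
    pixel-wise feed-forward neural network (ReLU hidden layers, sigmoid
    output, mini-batch gradient descent) classifies each pixel as seagrass
    or not. Binary maps are cleaned with sieve, median, bilateral or PCA
    filters, scored with overall, producer's and user's accuracy overall and
    by depth stratum, and compared across years to quantify meadow gain and
    loss. A seeded synthetic-scene simulator (exponential shallow-water
    reflectance model plus boat, swell, cloud and seasonal artifacts) makes
    every stage testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    igraph,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
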