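Package: rarefynet
Title: Refinement of Satellite NDVI Rasters of Row Crops with a UAV-Derived Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines decametric satellite-derived NDVI rasters of row crops,
    whose pixels mix canopy and inter-row soil radiometry, using a single
    co-registered high-resolution UAV-derived canopy NDVI raster as training
    reference. The refinement model is a light-weight residual inception
    convolutional network trained on 3x3x2 patch tensors (NDVI values plus
    pixel-location encoding) with ring-rotation data augmentation and the
    AdamW update rule. Also provides a K-means (k-means++ seeded,
    multi-restart) three-class vigor classifier for management zoning,
    one-way ANOVA and Pearson-correlation validation of refined maps, and a
    synthetic vineyard scene generator (parallel rows, inter-row soil, smooth
    three-level vigor field, canopy-masked and mixed-pixel downsampling) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
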