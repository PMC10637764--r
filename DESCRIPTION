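Package: stripshade
Title: Shading Capacity Modelling for Maize-Soybean Strip Intercropping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies the direct solar radiation blocked by maize strips on
    adjacent soybean rows in strip intercropping systems. Implements a
    shading capacity model built from solar position geometry, daily
    partitioning of global radiation into direct and diffuse components,
    per-row shading distance and shading intervals, a shading-proportion
    integral over solar-elevation branches, and aggregation to per-strip and
    seasonal cumulative shading capacity. Includes a canopy-height-model
    stage that derives daily maize-soybean height differences from surface
    rasters via excess-green soil masking, height thresholding, percentile
    extraction and spline interpolation, sensitivity sweeps over height
    difference, planting direction and latitude, and synthetic-scene
    generators for testing the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
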