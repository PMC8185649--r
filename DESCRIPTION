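Package: memcurve
Title: Membrane Curvature, Edge Velocity, and Fluorescence Enrichment
    from Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Relates membrane geometry to fluorescent-protein recruitment in
    time-lapse fluorescence microscopy. Provides classical segmentation with
    sub-pixel spline-resampled boundaries, osculating-circle signed curvature,
    edge velocity from signed Euclidean distance transforms, angular binning of
    boundary properties, doughnut-mask enrichment scoring at closing
    transendothelial macroapertures (TEMs), flattening/lagging membrane
    classification with a rotation-based permutation null, nanoring diameter
    estimation from sub-pixel perimeters, colocalization and protrusion
    morphometrics, and a seeded synthetic-microscopy generator with analytic
    ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
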