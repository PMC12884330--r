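Package: phevents
Title: Single-Vesicle pHluorin Event Simulation and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and quantification of single synaptic-vesicle
    fusion events recorded by nanoscale pHluorin imaging. Provides a
    ground-truth-labelled synthetic data generator (quantal amplitude
    mixtures, two-component endocytic decay, dwell-time plateaus,
    retrieval-fraction categories, clustered release sites, rendered
    image stacks), event detection and subpixel 2D-Gaussian
    localization, per-event endocytosis kinetics (decay constant, dwell
    time, half-time, retrieval fraction and category), population
    statistics (release probability, UVR/MVR classification,
    bi-Gaussian mixture decomposition, ultrafast ratio), active-zone
    spatial statistics (convex hull, release-site clustering), and an
    end-to-end reproducible pipeline with inclusion filters and group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    matrixStats
Config/testthat/edition: 3
RoxygenNote: 7.3.3
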