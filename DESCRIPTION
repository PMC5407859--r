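Package: stereostair
Title: Stereocilia Height Reconstruction and Hair-Bundle Morphometry
    from SEM Tilt Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the staircase architecture of
    cochlear hair-cell stereocilia bundles from scanning electron
    microscopy (SEM) tilt-series measurements. Implements the forward
    projection model for tilted stereocilia under an SEM beam and its
    three inverse procedures (two-view solving, reference-angle
    solving, and front-view step inversion), morphometric statistics
    (staircase steps, relative heights, tip-diameter profiles,
    wedge-tip heights, tip-link classification, supernumerary counts),
    group-comparison statistics with Welch and Student t tests, and a
    synthetic three-dimensional bundle generator with dose-dependent
    mechanotransduction-blocker effect models that makes every inverse
    computation verifiable by forward/inverse round trip.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
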