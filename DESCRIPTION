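Package: spqc
Title: Quality Control Checks for Optoelectronic Motion Capture Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the random and systematic errors of an optoelectronic
    stereophotogrammetric (motion capture) system from two short recordings of
    a rigid calibration object: a static trial at the centre of the capture
    volume, scored by the expanded uncertainty (sample standard deviation of
    the inter-marker geometry error times a coverage factor k), and a dynamic
    sweep of the volume, scored by the root-mean-square error against the
    object's nominal inter-marker distances and angles. Reads c3d and CSV
    marker trajectories, takes object geometry from a declarative JSON config,
    assembles an automated QC report (JSON, Markdown, HTML), and ships a
    rigid-body trial simulator with controllable Gaussian noise and systematic
    distortion fields so the whole pipeline is testable without laboratory
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
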