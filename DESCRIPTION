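Package: mdsm
Title: Multi-Platform Density Surface Models for Distance Sampling Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits density surface models that combine count data from several
    survey platforms, each with its own detection process: conventional and
    multiple-covariate distance sampling (half-normal and hazard-rate detection
    functions, exact or binned distances, line or point transects), independent
    observer double-platform mark-recapture distance sampling for imperfect
    detection on the trackline, and strip or plot transects with certain
    detection. Per-platform detectability enters a penalized-spline count model
    of segment counts as an offset; detection-function uncertainty is
    propagated into the spatial model by a fixed-prior random-effect refit, and
    abundance with uncertainty is obtained by posterior simulation of the model
    coefficients. Includes a survey simulator with known truth, delimited-text
    readers and writers, broom-style tidiers, and ggplot2 methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    mgcv
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    tools,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
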