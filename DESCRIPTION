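Package: sipsense
Title: Fluid-Intake Estimation from Container-Attached Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates per-drink volume and bottle fill level from the
    triaxial accelerometer trace of a container-attached inertial sensor.
    Implements the full analysis pipeline: bias estimation and signal
    conditioning, gravity-based inclination and cross-sectional angle
    estimation, threshold-based segmentation of drinking macro-events and
    lift/sip/place micro-events, a 33-feature inclination-signature
    descriptor, support vector regression of drink volume and fill ratio
    under leave-one-trial-out validation, and aggregate-consumption error
    metrics (MAPE and MOAPE). Ships a seeded simulator of scripted
    drinking trials so every stage can be exercised end to end without
    access to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    e1071,
    pracma,
    zoo,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    knitr,
    rmarkdown,
    optparse,
    yaml,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
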