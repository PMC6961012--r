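Package: actisma
Title: Adjustable Activity Classification for Thigh-Worn Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies tri-axial thigh-worn accelerometer recordings into
    dynamic, standing and sedentary behaviour using windowed signal magnitude
    area (SMA) of the body-acceleration component and a gravity-orientation
    threshold on the longitudinal axis. Provides the three adjustable
    parameters of the decision tree (segmentation window size, physical
    activity threshold, sensor orientation threshold), a sequential
    window-size / activity-threshold optimization procedure, validation
    statistics (percentage error, absolute percentage error, Bland-Altman
    limits of agreement, ICC(2,1)), and a synthetic-data generator emulating
    fixed and simulated free-living activity protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
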