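Package: forayr
Title: Detecting Extra-Territorial Prospecting Forays from Automated
    Radio-Tracking Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying extra-territorial prospecting behaviour of
    territorial animals tracked with fixed receiver arrays (e.g. Encounternet)
    that log identity-coded tag pulses with received signal strength (RSSI).
    Detection logs are windowed into per-epoch "best estimate" station-level
    locations via a conservative decision tree, location series are segmented
    into extra-territorial forays with duration and distance metrics, and
    foray rates are summarised per day and per hour of day.  Includes
    RSSI-distance calibration of the receiver array, a ground-truthed
    synthetic deployment simulator for validating every pipeline stage, and
    the behavioural statistics built on pipeline outputs: an exact binomial
    sex test, trailing prospecting-rate covariates, and a Poisson mixed model
    of the trade-off between prospecting and cooperative provisioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
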