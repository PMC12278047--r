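Package: oaextremes
Title: Ocean Warming and Acidification Extreme-Day Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnoses ocean warming and acidification extreme days in gridded
    daily surface fields (sea surface temperature, hydrogen ion concentration,
    pCO2, aragonite saturation state) under contrasting threshold definitions:
    seasonally constant and seasonally varying percentile thresholds, fixed
    historical and adaptive rolling-baseline reference periods, absolute
    thresholds (aragonite undersaturation, hypercapnia), and the degree
    heating weeks coral thermal-stress metric. Includes the annual-extreme
    monthly mean (AMM) percentile proxy and its calibration, compound
    multi-stressor event accounting, detrended percentile-change statistics,
    joint-distribution overlap analysis, site extraction, and a deterministic
    synthetic scenario generator emulating Earth-system-model daily output
    (seasonal cycle, scenario trends, AR(1) noise, cross-variable coupling)
    so that every stage of the analysis is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
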