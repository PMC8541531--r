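Package: bovitals
Title: Non-Invasive Video Biometrics and Milk Productivity Modelling for Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts heart rate and respiration rate from RGB video of dairy
    cows by remote photoplethysmography (green-channel and CIELab a* region
    means with band-pass filtering and peak analysis), abrupt-movement metrics
    from head-centroid tracks, and eye temperature from radiometric thermal
    frame stacks.  Derives dew-point and wet-bulb temperatures and a suite of
    nine temperature-humidity indices from farm weather records, assembles a
    37-column feature table, and fits a two-layer feedforward neural network
    trained by Bayesian-regularized Levenberg-Marquardt to predict eye
    temperature, milk yield (per day and per milking) and milk composition
    (fat and protein percentages).  Includes a synthetic-data generator that
    emulates the recording setup with known ground truth, so the whole
    pipeline is testable without farm recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
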