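Package: herblabor
Title: Learning-Curve Labor Estimation for Natural History Collections Digitization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning herbarium digitization projects from technician
    session reports. Cleans raw work-session logs (setback free text,
    swapped-field entry errors, extreme outliers, flagged reporters), computes
    per-technician cumulative task experience, bins specimen-per-minute rates
    into two-hour experience bins and fits experience-dependent rate curves by
    least squares, and runs a discrete-time turnover simulation that converts
    the fitted curves into labor-hour projections for barcoding, imaging, and
    skeletal databasing across contract durations and specimen counts. Includes
    a synthetic session-report generator with ground-truth anomaly labels so
    every pipeline stage is testable without access to project data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stringr,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
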