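Package: persched
Title: Personalized Scheduling of Biomarker Measurements via Joint Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for comparing personalized and fixed
    screening schedules of serially measured biomarkers in chronic heart
    failure. Generates synthetic cohorts emulating a prospective trimonthly
    kidney-biomarker study with a composite cardiac endpoint, fits a joint
    model for the longitudinal biomarker and the time-to-event outcome,
    derives subject-specific dynamic risk predictions, schedules measurements
    by a cumulative-risk threshold combined with expected Kullback-Leibler
    information gain, and evaluates measurement burden and timeliness of
    high-risk identification against a fixed trimonthly scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    nlme,
    survival,
    pracma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
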