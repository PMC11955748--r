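Package: pupilflow
Title: Pupillometry Preprocessing and Bayes Factor Time-Course Analysis for
    Infant Eye-Tracking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for violation-of-expectation pupillometry studies with
    infant eye-tracking data. Implements a preprocessing cascade from raw
    binocular samples to baseline-corrected relative pupil change on a fixed
    outcome-phase grid (artifact filtering by neighbour-difference
    percentiles, gap interpolation, binocular averaging, percent-change
    baseline correction, median-absolute-deviation outlier removal, and
    trial/subject inclusion rules), default-prior Bayes factor contrasts
    (JZS t-tests, BIC-approximated linear mixed models, signed-rank and
    binomial tests) with an evidence-classification scheme, time-resolved
    per-timepoint contrasts with evidence-window detection, fixation
    detection with area-of-interest scoring of anticipatory looking, a
    Bayesian sequential-design simulator, and a synthetic-data generator
    that emulates 120 Hz binocular recordings with planted condition
    effects, blinks, and scripted gaze for fully reproducible end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
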