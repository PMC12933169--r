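Package: stepdays
Title: Minimum Monitoring Days for Reliable Wearable Step-Count Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines how many days of wearable step-count monitoring are
    needed to reliably estimate short-term (7-day) and medium-term (28-day)
    habitual physical activity, separately for clusters of subjects with
    similar activity patterns. Implements wear-time validation of timestamped
    device streams (nonwear gaps exceeding 60 minutes, 10-hour waking wear
    minimum), valid-period selection (7 valid days in 10, or 28 in 40),
    agglomerative complete-linkage clustering on the four distributional
    moments of daily steps, and Monte-Carlo day-subset resampling of one-way
    random-effects intraclass correlation coefficients against the full-period
    mean, with minimum-days rules at an ICC threshold of 0.80. A synthetic
    cohort generator with Fleishman-transform day counts and simulated wear
    streams supports calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
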