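Package: alarmsim
Title: Vital-Sign Alarm Simulation for Remote Patient Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study alarm burden in healthcare-at-home programmes that
    monitor patients with continuous wearable sensors. The package smooths
    continuous pulse-rate, oxygen-saturation and respiratory-rate streams with
    time-windowed rolling medians, downsamples them to clinical observation
    schedules, replays declarative threshold/combination alarm rulesets over
    the resulting streams, and summarises the outcome as alarm-burden and
    early-detection metrics over 4-hour assessment windows. A synthetic cohort
    generator reproduces the adherence structure and vital-sign distributions
    of a healthcare-at-home population so the full pipeline can be exercised
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
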