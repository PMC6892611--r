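Package: mosaccade
Title: Saccade Detection, Calcium-Imaging Selectivity and Recovery Statistics
    for a Visually Guided Eye-Movement Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for head-fixed mouse experiments in which a
    cortical eye-movement area is optogenetically suppressed while the animal
    performs a visually guided eye-movement task. Detects saccades in 500 Hz
    eye-position traces by amplitude and speed thresholds, scores trials into
    outcomes with reaction times, turns two-photon movies or ROI fluorescence
    into trial-aligned dF/F and movement-related activity, classifies neurons
    as movement-related and direction-selective by rank tests, computes the
    contraversive/ipsiversive selectivity index with a shared-denominator
    before/after pairing, and summarises behavioral suppression and recovery
    with median +/- m.a.d., threshold proportions, Pearson chi-square and
    Mann-Whitney contrasts. A seeded synthetic-session generator (eye traces,
    trial schedules, GCaMP-like fluorescence, jittered movies) provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
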