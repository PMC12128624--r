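Package: fesgait
Title: Gait Analysis and Multi-Channel FES Sequencing for Overground
    Walking Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing overground walking assessments in
    neurorehabilitation: gait-event detection (foot contact, foot off)
    from markerless ankle and spine-base trajectories, spatiotemporal
    parameters (walking speed, step length, step width, cadence) within
    a 2-8 m measurement window, surface EMG linear-envelope processing
    with stride normalisation and a stimulated/non-stimulated activity
    ratio, an event-triggered multi-channel functional electrical
    stimulation (FES) scheduler, and feasibility-log analytics
    (adherence, technical issues, questionnaires, training distance).
    Includes a seeded synthetic gait and EMG generator so the whole
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
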