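Package: circadia
Title: Circadian Analysis of Actigraphy, Distal Skin Temperature and
    Heart-Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for chronobiological and autonomic analysis of
    ambulatory recordings: Cole-Kripke sleep-wake scoring of wrist
    actigraphy with sleep-parameter summaries, least-squares cosinor
    fitting of distal skin temperature rhythms (MESOR, amplitude,
    acrophase, percent rhythm), time-domain and discrete-wavelet-transform
    frequency-domain heart-rate-variability analysis of 24-h RR-interval
    recordings segmented into 30-min fragments and averaged by
    actigraphy-defined sleep and wake states, and the group-comparison and
    Bonferroni-screened correlation statistics that link autonomic
    physiology to cognitive scores.  Includes a synthetic-cohort generator
    with known ground truth so every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
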