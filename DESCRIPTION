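Package: poincareHRV
Title: Real-Time Poincare SD1/SD2 Monitoring of Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous, non-invasive characterization of autonomic function
    from heart-rate recordings via Poincare plot descriptors. Standardizes
    heart-rate or beat-annotation input to a uniformly sampled 1 Hz
    instantaneous heart-rate signal, removes ectopic/noise samples with a
    relative-threshold filter, computes the Poincare ellipse descriptors SD1
    (short-term variability, perpendicular to the line of identity) and SD2
    (long-term variability, along it), tracks them over a sliding window both
    in batch and as an online streaming engine, and compares pre-induction
    versus maintenance anesthesia stages with rank-sum tests. Includes a
    seeded synthetic heart-rate generator (first-order autoregressive noise
    plus a respiratory sinusoid) with closed-form expected descriptors, so the
    whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    optparse,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
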