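Package: seismogait
Title: Gait Analysis from Floor-Vibration Seismograph Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts footstep events from floor-mounted seismograph
    recordings by compound top-hat filtering (1-D grayscale mathematical
    morphology) and constrained peak detection, and derives clinical
    spatiotemporal gait parameters (step time, cycle time, ambulation
    time, cadence, velocity, step length) and timed up-and-go (TUG)
    timings from the event timestamps. Includes a multi-sensor walk
    simulator with known ground truth and the method-agreement battery
    (paired t-tests with Cohen's d, simple linear regression with
    F-test, Pearson correlation with Fisher confidence intervals, and
    Bland-Altman limits of agreement) used to validate vibration-based
    gait measurements against a reference system.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    rlang,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
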