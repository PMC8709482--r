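Package: semp
Title: Simulation and Analysis of Spinally Evoked Motor Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying task-dependent modulation of spinally evoked
    motor potentials (SEMPs) elicited by transcutaneous spinal stimulation
    doublets during movement preparation and performance. Provides a
    synthetic-session generator (multi-channel surface EMG, force, and event
    tables with condition-test-interval structure), peak-to-peak extraction of
    paired (R1/R2) responses with artifact blanking, recruitment-curve and
    reaction-time measurement, a normality-routed paired testing pipeline with
    Bonferroni correction for condition-test-interval modulation against
    no-movement controls, post-activation depression (R2/R1) ratios, and
    facilitation/inhibition exceedance-probability maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    readr,
    data.table,
    signal,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
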