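Package: wheelrun
Title: Wheel-Running Activity Analysis for Reed-Switch Logger Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing voluntary wheel-running recorded with
    magnetic reed-switch data loggers. Covers the full data path: debounced
    rotation detection from raw switch-edge streams (non-retriggerable
    lockout), minute-binned logger records, the per-day session CSV dialect
    with reconstruction of absolute time from a manual reset log, daily
    distance/duration/speed metrics with auditable exclusion rules, weekly
    group summaries, double-plotted actogram and cohort heatmap matrices,
    rotation-density summaries, and a circadian bouted-running simulator
    with known ground truth so every stage can be validated end to end.
    Includes a bill-of-materials and print-plan validator for the
    open-source 3D-printed wheel hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
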