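Package: breathloop
Title: Breathing Biofeedback Scoring and Single-Case Withdrawal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for offline analysis of breathing-based biofeedback
    training delivered inside an arousing decision-making task. Implements
    the sliding-window spectral biofeedback score (power in the 6-10
    breaths/min band relative to total breathing power, 30 s windows
    updated every 2 s), heart-rate-variability band powers and
    breathing-LF coherence from R-R interval series, signal-detection and
    priming metrics from shoot/don't-shoot event logs, and the
    single-case experimental design (SCED) withdrawal statistics:
    15 s binning, phase trends, Kendall cross-pair tau non-overlap
    contrasts with meta-aggregation, the six-feature visual-analysis
    summary, and repeated-measures correlation. A deterministic synthetic
    cohort generator (chirp breathing traces, integrate-and-fire R-R
    emission with respiratory sinus arrhythmia, Gaussian-observer game
    agents, ABBABABABA learning dynamics) provides ground-truth data for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
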