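Package: premove
Title: Decoding Self-Initiated Actions from Pre-Movement Cortical Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for multi-second pre-movement dynamics in
    area-level widefield calcium imaging time series recorded during
    self-initiated behavior. Provides a synthetic session generator with
    implanted ground truth (slow oscillations, pre-event ramps, phase
    concentration at action onset, variance changes), peri-event trial
    extraction with behavioral lockout rules, sliding-window support vector
    machine decoding with an earliest-decoding-time (EDT) statistic based on
    a Benjamini-Hochberg corrected backward walk, single-trial sinusoid fits
    and circular phase statistics at movement onset, Welch power spectra of
    slow oscillations, convex-hull neural state-space analysis, and
    detection of pre-movement trial-to-trial variance changes (EVDT).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    grDevices,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
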