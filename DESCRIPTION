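Package: cmrpv
Title: Dynamic Pressure-Volume Loop Analysis for Real-Time CMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives dynamic left-ventricular pressure-volume (PV) loops
    acquired during an inferior-vena-cava occlusion in the cardiovascular
    magnetic resonance (CMR) environment. Synchronizes invasive pressure,
    ECG and MR gradient-waveform recordings with real-time long-axis cine
    contours, computes ventricular volume by centerline rotation, detects
    per-beat end-diastolic and end-systolic fiducials, pairs pressure and
    volume into per-beat loops, and quantifies contractility (ESPVR slope)
    and compliance (inverse EDPVR slope). Includes Bland-Altman and
    intraclass-correlation agreement statistics and a lumped-parameter
    time-varying-elastance simulator with preload decay so that every
    pipeline stage is testable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
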