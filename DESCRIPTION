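Package: reswave
Title: Reservoir-Wave Decomposition and Wave Intensity Analysis of
    Arterial Pressure and Velocity Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes arterial pressure and flow-velocity waveforms into
    reservoir and excess components under the reservoir-wave model, with the
    diastolic exponential decay fitted by four interchangeable techniques
    (two or three free parameters, whole diastole or its last two thirds).
    Provides downstream wave intensity analysis (PU-loop wave speed,
    forward/backward intensity separation, compression and expansion wave
    areas), scalar hemodynamic parameters, preprocessing of raw tonometry-like
    recordings (beat segmentation, ensemble averaging, calibration, alignment,
    dicrotic-notch detection), a synthetic carotid waveform generator with
    known ground truth for validation, and cohort-level comparison statistics
    across fitting techniques.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
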