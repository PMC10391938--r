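Package: cyclebursts
Title: Cycle-by-Cycle Detection of EEG Oscillation Bursts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects theta and alpha oscillation bursts in wake EEG by
    cycle-by-cycle waveform analysis: narrowband equiripple FIR filtering,
    zero-crossing and peak parsing, seven per-cycle shape and regularity
    criteria, dual-polarity detection, within-channel overlap resolution and
    cross-channel aggregation into reference bursts. Companion analyses
    include Welch power spectral density with pooled z-scoring, pupillometry
    (eye-closure classification, pixel-to-millimetre calibration, oddball
    pupil responses) and session-level statistics (paired t-tests with
    Hedges' g, a wake-maintenance-zone interpolation contrast,
    Benjamini-Hochberg correction and minimum-detectable-effect power
    analysis). Ships a synthetic-data module that generates EEG, oddball and
    pupil fixtures with ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
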