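Package: prvagree
Title: Validation of Pulse Rate Variability Against ECG-Derived Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for validating pulse rate variability (PRV)
    measured by a photoplethysmography (PPG) sensor against heart rate
    variability (HRV) from a reference ECG device. Provides a synthetic
    dual-sensor cohort generator with LF/HF oscillatory modulation and
    pulse-transit-time jitter, PPG beat detection (low-pass, derivative,
    squaring, dynamic threshold), beat-level series alignment, interbeat
    artifact detection and repair, the standard short-term HRV feature set
    (mean, SDNN, pNN50, RMSSD, Lomb-Scargle LF/HF band powers, Poincare
    SD1/SD2), a method-agreement battery (coefficient-of-variation
    differences, Hedges's g, Lin's concordance correlation with a
    Shapiro-Wilk gate, Bland-Altman limits of agreement and ratio), and a
    paired rest-versus-stress comparison (Wilcoxon signed rank with
    common-language effect size).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
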