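Package: mirrorvitals
Title: Contactless Vital-Sign Estimation from Facial Video Streams
Version: 0.1.0
Authors@R:
    person("Mirror", "Vitals Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Streaming remote-photoplethysmography (rPPG) toolkit for
    camera-based vital-sign monitoring. Implements chrominance-based pulse
    extraction from spatially averaged facial RGB traces, FIR bandpass
    filtering, FFT heart-rate estimation with sub-bin peak interpolation,
    ratio-of-ratios SpO2 estimation, quality-gated sliding-window streaming
    with multimodal chatbot-trigger logic and bilingual prompt assembly, a
    synthetic scene generator with known physiological ground truth, and
    Bland-Altman/MAE/Pearson agreement evaluation against reference series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
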