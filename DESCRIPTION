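Package: ecodetect
Title: On-Device-Style Acoustic Event Detection for Ecological Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desktop implementations of three low-power acoustic detection
    algorithms used on autonomous field recorders: Goertzel-filter narrowband
    energy extraction, a sliding-median detector for ultrasonic bat
    echolocation pulses, a dual-band spectral-ratio detector for sustained
    cicada song that rejects wind noise, and a five-state hidden Markov model
    with log-normal emissions and Viterbi decoding for gunshot detection.
    Includes supervised HMM training from labelled audio, detector evaluation
    (precision, recall, F1, ROC, AUC, FPR-capped threshold selection),
    deployment resource estimators (storage, battery, false-trigger budgets),
    a seeded synthetic-audio fixture generator, WAV/CSV/YAML/JSON input and
    output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
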