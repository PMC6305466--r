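Package: eegworkload
Title: EEG-Based Mental Workload Index from Spectral Features and
    Stepwise Discriminant Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes an electroencephalography (EEG) based mental
    workload neurometric at 8-second resolution from multichannel scalp
    recordings. The pipeline band-pass filters the signal, removes
    eye-blink contributions using the forehead (FPz) channel, segments the
    data into 2-second sliding epochs, rejects artifact epochs by
    amplitude, trend and sample-to-sample criteria, extracts
    Hanning-windowed power spectral density features in frontal-theta and
    parietal-alpha bands anchored to the Individual Alpha Frequency, and
    trains a stepwise linear discriminant with an automatic stopping rule
    to map easy (0) versus hard (1) task conditions. Includes the full
    evaluation battery (ROC-AUC with shuffled-label baseline, Wilcoxon and
    Friedman tests with false-discovery-rate correction, condition and
    event-window aggregation, NASA-TLX scoring) and a synthetic EEG
    session generator with ground truth for end-to-end verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
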