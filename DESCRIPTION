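Package: rppgscreen
Title: Contact-Free Depression Screening from Facial-Video Pulse Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for web-camera remote photoplethysmography
    (rPPG) screening of major depressive disorder from task-evoked autonomic
    responses. Extracts a blood-volume-pulse signal from the facial
    green-channel trace by maximal-overlap discrete wavelet multiresolution
    filtering (symlet-4, level 4) with a 0.6-2.0 Hz cardiac band-pass,
    converts it to a cleaned interbeat-interval series, computes LF/HF
    heart-rate-variability spectra per protocol period (pre-rest, mental
    task, post-rest), and screens subjects with a minimum-redundancy
    maximum-relevance selected logistic model, including the published
    four-variable screening equation. Ships an integral-pulse-frequency
    modulation (IPFM) session simulator (beats, reference ECG, pulsatile
    facial RGB traces, rendered synthetic frames, cohorts) so every stage is
    testable without clinical recordings, plus ECG agreement statistics
    (Pearson, RMSE, Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
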