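Package: asrnoise
Title: Simulated Speech Recognition Intelligibility Experiments in
    Multi-Talker Babble Noise
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for running reproducible speech-intelligibility-in-noise
    experiments with a simulated automatic speech recognition (ASR) backend.
    Builds N-talker babble noise from single-talker clips (silence trimming,
    moving-window spectral equalization, sex-balanced combination), mixes
    speech and babble at exact signal-to-noise ratios, scores hypothesis
    transcripts against ground truth by the best order-preserving word
    alignment, and compares groups (for example dysarthric and healthy
    speakers) with rank-based nonparametric tests. A synthetic-data module
    generates sentence corpora, speaker cohorts and speech-like waveforms so
    the full pipeline is testable end to end without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    withr
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
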