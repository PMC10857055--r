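Package: triad
Title: Codec, Synchronization, and Validation Statistics for Multimodal
    Infant-Wearable Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with chunked multimodal recordings from an
    infant-wearable sensing platform that captures electrocardiogram (ECG,
    2426 Hz), 9-axis inertial data (nominally 70 Hz), and audio (22050 Hz)
    in timestamped binary chunks. Provides a self-describing binary codec
    with explicit missing-sample accounting, UTC-based frame
    synchronization, R-peak detection and interbeat-interval (IBI) artifact
    editing, respiratory sinus arrhythmia (RSA) estimation by the
    Porges-Bohrer moving-polynomial method with adult and infant
    respiration bands, accelerometer activity recognition, audio
    preprocessing (polyphase downsampling, declipping) with a speech
    emotion recognition cross-validation pipeline, device-agreement
    statistics (MAPE, Bland-Altman limits of agreement, Cohen's kappa,
    weighted F1, McNemar's test, word error rate), and seeded synthetic
    signal generators for end-to-end validation of the full processing
    chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
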