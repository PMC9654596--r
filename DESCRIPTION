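Package: eegcnn
Title: Band-Power Features and Residual 1D Convolutional Networks for
    EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window FFT band-power feature extraction from
    DEAP-style 32-channel EEG recordings, rating-based feature extension,
    and lightweight residual one-dimensional convolutional network
    classifiers for binary valence/arousal recognition.  Includes a
    seeded synthetic-EEG generator with a plantable band-power to rating
    dependence so the full pipeline is testable without access to the
    original dataset, five architecture variants with verified trainable
    parameter counts, training with Adam and categorical cross-entropy,
    per-class evaluation reports, and window-size and train-split sweep
    harnesses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
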