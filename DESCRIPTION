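Package: midecoder
Title: Motor-Imagery EEG Decoding with WPD-CSP Features and EEGNet-LSTM
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decoders for motor-imagery electroencephalography (EEG)
    trials. Implements a feature pipeline combining wavelet packet
    decomposition (WPD) with common spatial patterns (CSP) feeding a
    two-layer long short-term memory (LSTM) classifier, and a hybrid
    decoder stacking the two EEGNet convolutional blocks in front of the
    same LSTM head. Includes zero-phase bandpass and notch filtering,
    window cropping, one-hot label encoding and per-trial min-max
    scaling; exhaustive hyperparameter grid search; a deterministic
    synthetic motor-imagery EEG generator with class-specific mu/beta
    rhythm modulation for testing without external recordings; and an
    evaluation layer computing accuracy, Cohen's kappa and paired
    Wilcoxon signed-rank comparisons across decoding methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
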