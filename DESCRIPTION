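Package: wheezr
Title: Wheeze Event Detection in Pediatric Smartphone Lung Auscultation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for automated wheeze detection in short (5-10 s)
    pediatric lung-sound recordings captured with smartphone microphones.
    Provides WAV input/output and audio preprocessing (resampling,
    band-pass filtering, peak normalization, fixed 10-s windowing with
    zero padding), a synthetic annotated lung-sound cohort generator,
    three feature representations (handcrafted spectral features,
    log-mel spectrograms, and Sobel-filtered mel spectrograms), a hybrid
    convolutional-recurrent (CNN+LSTM) frame-wise wheeze event detector
    with onset/offset decoding, any-window recording-level aggregation,
    and a diagnostic-accuracy statistics layer (confusion-matrix metrics
    with Wilson confidence intervals, Cohen and Fleiss kappa,
    chi-square/Fisher test selection with Bonferroni correction, and
    reconstruction of confusion tables from published aggregates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
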