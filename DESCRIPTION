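Package: ecgconvit
Title: ECG Beat Classification with Time-Reassigned Synchrosqueezing
    Spectrograms and a Convolutional Vision Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for heartbeat (arrhythmia) classification
    from single-lead ECG. Beats are cut into 300-sample windows around
    annotated R-peaks and mapped to the five AAMI classes (N, S, V, F, Q);
    each beat is converted to a time-frequency image with the time-reassigned
    synchrosqueezing transform (TSST), which relocates short-time Fourier
    coefficients to their group delay and so sharpens the impulsive QRS
    complex; class imbalance is handled with SMOTE oversampling in beat space
    and a focal loss; and a compact convolutional vision transformer (ConViT)
    with gated positional self-attention classifies the spectrogram images.
    Includes a synthetic five-class beat generator so the whole pipeline is
    testable without external data, a minimal WFDB record/annotation reader,
    and per-class evaluation metrics (accuracy, sensitivity, specificity,
    positive predictive value, F1, Matthews correlation, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    png,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
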