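Package: emgpr
Title: Surface EMG Pattern Recognition for Myoelectric Prosthetic Hand Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for two-channel surface electromyography (EMG)
    pattern recognition as used in myoelectric prosthetic hand control. Provides
    a synthetic labeled EMG session generator (amplitude-modulated band-limited
    noise with power-line interference and inter-subject variability), causal
    IIR bandpass and notch filtering in batch and streaming form, 100 ms window
    segmentation with four time-domain features (MAV, RMS, SSI, VAR),
    from-scratch k-nearest-neighbour, Gaussian naive Bayes, entropy decision
    tree and RBF-kernel support vector machine classifiers behind one
    fit/predict contract, pooled and subject-wise train/test evaluation with
    confusion matrices and timing, and a deterministic four-stage replay
    pipeline (acquisition, feature extraction, classification, motor control)
    driving a simulated prosthetic actuator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    rpart,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
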