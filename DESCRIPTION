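Package: pcgst
Title: Heart Sound Segmentation and S1/S2 Classification with the
    S-Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Locates and classifies the first (S1) and second (S2) heart
    sounds in single-channel phonocardiograms without an ECG reference,
    targeting cardiac stress-test conditions where systolic and diastolic
    interval criteria break down.  Segmentation uses a modified Shannon
    energy envelope of the alpha-parameterized Stockwell transform
    (S-transform); classification uses single-scalar time-frequency
    features: the concentration-optimal Gaussian width alpha_opt, the
    envelope time-integral beta, and the envelope kurtosis gamma, with a
    wavelet high-frequency-signature comparator.  Includes an annotated
    synthetic stress-test phonocardiogram generator and an evaluation
    harness (ROC/AUC, rank-sum tests, noise-robustness and heart-rate
    sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
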