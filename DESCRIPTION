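Package: s4decg
Title: Diagonal State-Space Sequence Models for Multi-Label ECG Abnormality Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements shallow stacked diagonal state-space sequence (S4D)
    classifiers for raw multi-lead electrocardiogram signals, including
    zero-order-hold discretization, closed-form convolution kernels evaluated
    by FFT, a full training loop (AdamW, cosine-annealed learning rate,
    binary cross-entropy), a class-conditioned synthetic 12-lead ECG
    generator, a classical denoising pipeline (Butterworth band-pass, db4
    wavelet shrinkage, baseline high-pass), multi-label evaluation metrics
    (F1, AUROC, AUPRC, support-weighted averages), and lead-ablation
    robustness protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
SystemRequirements: fftw3
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
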