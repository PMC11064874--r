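Package: stecg
Title: Hybrid Time-Frequency Denoising of ECG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Removes power-line interference, baseline wander, muscle
    artifact, electrode motion and broadband Gaussian noise from
    single-channel electrocardiogram (ECG) recordings with a hybrid
    time-frequency scheme: the Stockwell transform maps the signal to a
    complex time-frequency representation, bi-dimensional empirical mode
    decomposition splits the magnitude plane into multi-scale intrinsic
    mode functions, each mode is filtered by patch-based non-local means,
    and the inverse transform restores a clean time-domain trace.  Also
    provides the standard signal-quality metrics (SNR, RMSE, PRD, SSIM),
    seeded synthetic ECG and noise generators with exact input-SNR
    calibration, wavelet-threshold and time-domain non-local-means
    baseline denoisers, and a command-line interface for batch
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    mgcv,
    optparse,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
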