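Package: respfield
Title: Respiratory Field Regressors from the Phase of fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a respiratory regressor from the wrapped phase of
    gradient-echo EPI fMRI time series without external hardware. Each volume's
    phase is unwrapped with a spectral Laplacian method, the local tissue field
    is removed with regularized SHARP, and the residual harmonic background
    field is decomposed with a truncated singular value decomposition. The
    respiratory component is selected by maximal instantaneous variation of the
    scaled right singular vectors, projected onto real solid harmonics up to
    third order, and the zeroth-order coefficient is returned as the regressor.
    Includes breathing-belt trace preprocessing, respiratory phase synthesis
    (histogram and Hilbert methods), peak-based agreement metrics, and a
    ground-truth phantom simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
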