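Package: mdlhrf
Title: Haemodynamic Response Estimation for Event-Related fMRI via MDL
    Wavelet Denoising and FIR Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the haemodynamic response function (HRF)
    from event-related BOLD fMRI time series. Voxel time series are denoised
    by orthonormal discrete wavelet transform with minimum-description-length
    (crude and refined MDL) selection of the number of retained coefficients,
    activated voxels are detected by a scan-difference t-test with top-k
    selection, and the HRF is extracted both by epoch averaging with
    percent-change baseline normalisation and by finite-impulse-response
    deconvolution using a Moore-Penrose pseudo-inverse with per-run baseline
    regressors. Includes a synthetic event-related paradigm and BOLD
    generator with group-specific signal-to-noise levels, group-level peak
    amplitude comparisons, and a simulation harness for null calibration and
    power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
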