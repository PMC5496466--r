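# mdlhrf

Estimation of the haemodynamic response function (HRF) from event-related
BOLD fMRI time series, built for one scientific question: **do apparent group
differences in HRF peak amplitude (e.g. young vs elderly, healthy vs
demented) survive once noise is handled properly?** Epoch averaging — the
estimator behind most historical ageing comparisons — is badly behaved at low
SNR and with overlapping trials, and the set of "activated" voxels it is fed
is itself noise-dependent. `mdlhrf` implements the robust alternative chain
and the simulation machinery to study it:

1. **Synthetic event-related generator** with known ground truth: 4 runs ×
   128 volumes at TR 2.68 s, 60 trials (isolated and paired conditions,
   5.36 s intra-pair spacing, 21.44 s trial windows), group-specific SNR
   (peak/σ: 0.52 young, 0.35 elderly), optional AR(1) noise and slow drift.
2. **MDL wavelet denoising**: orthonormal Daubechies DWT; keep the `k`
   largest coefficients minimising the crude (C-MDL) cost
   `((n−k)/2)·ln((S−S_γ)/(n−k)) + (k/2)·ln(S_γ/k) + ½·ln k(n−k)` or the
   refined (R-MDL) cost
   `((n−k)/2)·ln((S−S_γ)/(n−k)³) + (k/2)·ln(S_γ/k³)`, searched over
   `1 ≤ k < 0.95·n`.
3. **Activation detection**: per-trial scan differences (third minus first
   scan of the trial window), one-sample t per voxel, top-32 positive-t
   selection, and overlap metrics between analysis states.
4. **HRF extraction** by epoch averaging (percent change about the first
   epoch scan) and by FIR deconvolution: `[h; b] = pinv(X) · y` with a
   `T × (L+1)` stick design whose ninth column estimates the baseline.
5. **Group statistics**: per-subject peak amplitudes from the mean ROI
   curve, Welch's t-test between groups, and a replicated experiment driver
   for type-I calibration and power studies.

## Worked example

```r
library(mdlhrf)

cfg <- experiment_config()                       # the default paradigm
sim <- simulate_subject(cfg, group = "nondemented", seed = 42)
sim$dataset
#> BOLD dataset: 80 voxels x 124 scans x 4 run(s), TR 2.68 s, group 'nondemented'
#>   (4 initial volumes already discarded per run)

dn  <- denoise_dataset(sim$dataset, criterion = "rmdl")
vox <- select_top_voxels(tstat_map(dn), 32)
head(vox, 3)
#>   voxel_id        t rank
#> 1     v018 2.195888    1
#> 2     v036 2.061256    2
#> 3     v031 2.047593    3

roi <- mean_roi_hrf(dn, vox, method = "deconvolution")
roi$curve
#> HRF curve (deconvolution), 8 lags, percent signal change
#>   0.00s   2.68s   5.36s   8.04s  10.72s  13.40s  16.08s  18.76s
#> -0.0310  0.0554  0.1729  0.0213  0.0284  0.0416 -0.0127 -0.0377
hrf_peak(roi$curve)
#> peak 0.173% at 5.36 s
```

The subject's response peaks at 5.36 s (the third post-onset scan), as the
generator's ground truth dictates; at elderly SNR the R-MDL thresholding has
also shrunk the amplitude well below the true 1% — amplitude attenuation at
low SNR is a property of aggressive MDL thresholding worth knowing about.

A small replicated group experiment (all four analysis variants):

```r
res <- run_experiment(cfg, n_subjects = c(young = 4L, nondemented = 4L),
                      n_replicates = 2L, seed = 1L)
res[, c("replicate", "method", "denoise", "t", "p", "significant")]
#>   replicate        method denoise        t      p significant
#> 1         1     averaging    none -1.13967 0.3155       FALSE
#> 2         1 deconvolution    none  0.31790 0.7628       FALSE
#> 3         1     averaging    rmdl  0.69890 0.5183       FALSE
#> 4         1 deconvolution    rmdl  0.54280 0.6073       FALSE
#> 5         2     averaging    none  0.00312 0.9977       FALSE
#> 6         2 deconvolution    none -0.01265 0.9907       FALSE
#> 7         2     averaging    rmdl -2.21434 0.0696       FALSE
#> 8         2 deconvolution    rmdl -1.54195 0.1823       FALSE
```

Both groups share the same ground-truth HRF here, so non-significance is the
correct outcome. `run_pipeline(pipeline_config(...), out_dir)` runs the same
chain end to end and writes per-stage TSV artifacts plus a JSON manifest;
events and time-series files round-trip through `read_events()` /
`write_timeseries()` (tab-separated text with a YAML sidecar, optional NIfTI).

## A negative result

The methods vignette (`vignettes/mdl-hrf-methods.Rmd`) documents one
deliberate test failure: under a true null with group SNRs 0.52 vs 0.35, the
full pipeline's Welch test rejects at ≈0.31 instead of 0.05, because top-32
rank selection reuses the same scans that enter the peak estimate (selection
circularity). With the ROI fixed to the truly active voxels the pipeline
calibrates. The estimators are sound; feeding them noise-selected voxels at
elderly SNR is not.

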