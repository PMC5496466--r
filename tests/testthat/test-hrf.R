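test_that("epoch averaging converts to percent change about the first scan", {
  curve <- epoch_average_hrf(c(100, 101, 103, 102, 101, 100, 100, 100),
                             onsets = 0, L = 8L)
  expect_equal(curve$samples, c(0, 1, 3, 2, 1, 0, 0, 0))
  expect_equal(curve$lag_seconds, (0:7) * 2.68)
  flat <- epoch_average_hrf(rep(100, 40), onsets = c(0, 10, 20), L = 8L)
  expect_equal(flat$samples, rep(0, 8))
  expect_warning(tr <- epoch_average_hrf(rep(100, 10), c(0, 5), L = 8L),
                 "truncated")
  expect_warning(bad <- epoch_average_hrf(c(-1, rep(1, 9)), 0, L = 4L),
                 "non-positive")
  expect_true(bad$flagged)
})

test_that("the design matrix is the FIR stick design with baseline column", {
  X <- build_design_matrix(c(2, 10), T_scans = 20, L = 8L)
  expect_equal(dim(X), c(20L, 9L))
  expect_equal(unname(X[, 9]), rep(1, 20))
  for (j in 0:7) {
    hits <- which(X[, j + 1] == 1)
    expect_equal(hits, c(2, 10) + j + 1)
  }
  expect_true(all(X %in% c(0, 1)))

  # onset 0 with T = L gives the identity lag block
  X2 <- build_design_matrix(0, T_scans = 8, L = 8L)
  expect_equal(unname(X2[, 1:8]), diag(8))

  # paired onsets 2 apart put two lag columns on the same rows
  X3 <- build_design_matrix(c(4, 6), T_scans = 20, L = 8L)
  expect_true(any(rowSums(X3[, 1:8]) == 2))

  # clipping at the run end
  X4 <- build_design_matrix(16, T_scans = 20, L = 8L)
  expect_equal(sum(X4[, 1:8]), 4)

  expect_error(build_design_matrix(integer(0), 20), "empty")
  expect_error(build_design_matrix(25, 20), "lie in")
})

test_that("deconvolution recovers h and baseline exactly from noiseless data", {
  h <- c(0, 1, 3, 2, 1, 0.5, 0, 0)
  b <- 100
  X <- build_design_matrix(c(3, 11, 13, 30), T_scans = 48, L = 8L)
  y <- as.numeric(unclass(X) %*% c(h, b))
  curve <- deconvolve_hrf(y, X)
  expect_equal(curve$raw$h, h, tolerance = 1e-10)
  expect_equal(curve$baseline_estimate, b, tolerance = 1e-10)
  expect_equal(curve$samples, 100 * h / b, tolerance = 1e-10)
})

test_that("deconvolution beats averaging under overlapping paired trials", {
  cfg <- noiseless_config()
  sim <- simulate_subject(cfg, "young", seed = 5)
  vox <- sim$dataset$voxel_ids[1]
  dec <- mean_roi_hrf(sim$dataset, vox, "deconvolution")$curve$samples
  avg <- suppressWarnings(
    mean_roi_hrf(sim$dataset, vox, "averaging")$curve$samples)
  truth_pct <- 100 * sim$truth$hrf / 100
  expect_equal(dec, truth_pct, tolerance = 1e-8)
  rmse <- function(x) sqrt(mean((x - truth_pct)^2))
  expect_gt(rmse(avg), 1e-3)  # averaging is biased by overlap
  expect_lt(rmse(dec), 1e-8)  # deconvolution is exact
})

test_that("a zero series yields zero h, zero baseline, and a flag", {
  X <- build_design_matrix(c(2, 12), T_scans = 30, L = 8L)
  expect_warning(curve <- deconvolve_hrf(rep(0, 30), X), "non-positive")
  expect_equal(curve$raw$h, rep(0, 8))
  expect_equal(curve$baseline_estimate, 0)
  expect_true(curve$flagged)
})

test_that("rank-deficient designs warn and return the minimum-norm solution", {
  # single onset at 0 with T = L: lag block = identity, so the baseline
  # column is a linear combination of responses and rank drops
  X <- build_design_matrix(0, T_scans = 8, L = 8L)
  expect_warning(curve <- deconvolve_hrf(rep(100, 8), X), "rank-deficient")
  expect_true(all(is.finite(curve$raw$h)))
})

test_that("averaging and deconvolution agree on isolated noiseless trials", {
  onsets <- c(4L, 16L, 36L)
  cfg <- experiment_config(volumes_per_run = 56L, n_runs = 1L,
                           trials_per_run = 3L, n_active_voxels = 3L,
                           n_inactive_voxels = 1L,
                           group_snr = c(young = Inf))
  ev <- data.frame(run = 1L, trial = 1:3, onset_scan = onsets,
                   onset_seconds = onsets * cfg$tr_seconds,
                   condition = "isolated")
  sched <- mdlhrf:::new_event_schedule(ev, cfg$tr_seconds)
  truth <- ground_truth(cfg, "young")
  dat <- synthesize_bold(sched, truth, cfg, seed = 6)
  vox <- dat$voxel_ids[1:3]
  avg <- mean_roi_hrf(dat, vox, "averaging")
  dec <- mean_roi_hrf(dat, vox, "deconvolution")
  expect_equal(avg$curve$samples, dec$curve$samples, tolerance = 1e-6)
  # identical voxels: SEM is zero at every lag
  expect_equal(avg$sem, rep(0, 8), tolerance = 1e-10)
})

test_that("the ROI SEM is the across-voxel sd over sqrt(n)", {
  cfg <- small_config()
  sim <- simulate_subject(cfg, "young", seed = 7)
  vox <- sim$dataset$voxel_ids[1:10]
  roi <- mean_roi_hrf(sim$dataset, vox, "deconvolution")
  expect_equal(roi$n_used, 10L)
  expect_equal(roi$sem, apply(roi$per_voxel, 2, sd) / sqrt(10),
               tolerance = 1e-12)
  expect_equal(roi$curve$samples, colMeans(roi$per_voxel), tolerance = 1e-12)
})
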