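test_that("noiseless single impulse reproduces baseline plus HRF", {
  cfg <- noiseless_config()
  truth <- ground_truth(cfg, "young")
  # one isolated onset at scan 10 of run 1, nothing in run 2
  ev <- data.frame(run = c(1L, 2L), trial = c(1L, 2L),
                   onset_scan = c(10L, 40L),
                   onset_seconds = c(10L, 40L) * cfg$tr_seconds,
                   condition = "isolated")
  sched <- mdlhrf:::new_event_schedule(ev, cfg$tr_seconds)
  dat <- synthesize_bold(sched, truth, cfg, seed = 1)
  y <- dat$runs[[1]][1, ] # active voxel
  expect_equal(unname(y[10 + (1:8)]), 100 + truth$hrf)
  expect_equal(unname(y[-(10 + (1:8))]),
               rep(100, cfg$volumes_per_run - 8))
  # inactive voxel carries no response
  expect_equal(unname(dat$runs[[1]][cfg$n_active_voxels + 1L, ]),
               rep(100, cfg$volumes_per_run))
})

test_that("SNR definition fixes the noise standard deviation", {
  cfg <- experiment_config()
  truth <- ground_truth(cfg, "young")
  expect_equal(max(truth$hrf), 1)
  expect_equal(truth$noise_sd, 1 / 0.52, tolerance = 1e-12)
  expect_equal(ground_truth(cfg, "nondemented")$noise_sd, 1 / 0.35,
               tolerance = 1e-12)
})

test_that("empirical noise sd of an inactive voxel matches noise_sd", {
  cfg <- experiment_config(n_active_voxels = 1L, n_inactive_voxels = 1L,
                           volumes_per_run = 4096L, n_runs = 1L,
                           trials_per_run = 1L)
  truth <- ground_truth(cfg, "nondemented")
  sched <- generate_paradigm(cfg, seed = 3)
  dat <- synthesize_bold(sched, truth, cfg, seed = 3)
  emp <- sd(dat$runs[[1]][2, ])
  expect_equal(emp, truth$noise_sd, tolerance = 0.05)
})

test_that("mean epoch response converges to the HRF as noise vanishes", {
  # well-separated isolated events, so epochs are overlap-free
  onsets <- c(5L, 25L, 45L)
  ev <- data.frame(run = 1L, trial = seq_along(onsets), onset_scan = onsets,
                   condition = "isolated")
  err <- vapply(c(0.35, 5, Inf), function(snr) {
    cfg <- experiment_config(volumes_per_run = 64L, n_runs = 1L,
                             trials_per_run = 3L,
                             n_active_voxels = 2L, n_inactive_voxels = 2L,
                             group_snr = c(young = snr))
    ev$onset_seconds <- ev$onset_scan * cfg$tr_seconds
    sched <- mdlhrf:::new_event_schedule(ev, cfg$tr_seconds)
    truth <- ground_truth(cfg, "young")
    dat <- synthesize_bold(sched, truth, cfg, seed = 11)
    curve <- epoch_average_hrf(dat$runs[[1]][1, ], onsets, L = 8L,
                               tr_seconds = cfg$tr_seconds)
    truth_pct <- 100 * truth$hrf / 100
    sqrt(mean((curve$samples - truth_pct)^2))
  }, numeric(1))
  expect_true(all(diff(err) < 0))       # error shrinks with SNR
  expect_lt(err[3], 1e-8)               # exact in the noiseless limit
})

test_that("generation is reproducible and seeds matter", {
  cfg <- small_config()
  a <- simulate_subject(cfg, "young", seed = 5)
  b <- simulate_subject(cfg, "young", seed = 5)
  expect_identical(a$dataset$runs, b$dataset$runs)
  c <- simulate_subject(cfg, "young", seed = 6)
  expect_false(identical(a$dataset$runs, c$dataset$runs))
})

test_that("ar1 noise and drift options produce valid datasets", {
  cfg <- small_config(noise_model = "ar1", drift_amplitude = 0.5)
  sim <- simulate_subject(cfg, "nondemented", seed = 9)
  Y <- sim$dataset$runs[[1]]
  expect_true(all(is.finite(Y)))
  # AR(1) noise is positively autocorrelated at lag 1
  inact <- Y[cfg$n_active_voxels + 1L, ]
  expect_gt(cor(inact[-1], inact[-length(inact)]), 0.1)
})

test_that("discarding initial volumes trims runs and shifts onsets", {
  cfg <- experiment_config()
  truth <- ground_truth(cfg, "young")
  sched <- generate_paradigm(cfg, seed = 2)
  dat <- synthesize_bold(sched, truth, cfg, seed = 2)
  expect_equal(ncol(dat$runs[[1]]), 128L)
  trimmed <- discard_initial_volumes(dat, cfg)
  expect_equal(ncol(trimmed$runs[[1]]), 124L)
  expect_equal(trimmed$schedule$onset_scan, sched$onset_scan - 4L)
  expect_equal(trimmed$runs[[1]], dat$runs[[1]][, -(1:4)])
  # discard 0 is the identity
  expect_identical(discard_initial_volumes(dat, 0L), dat)
})

test_that("events starting before the new origin are dropped with a message", {
  cfg <- noiseless_config()
  truth <- ground_truth(cfg, "young")
  ev <- data.frame(run = 1:2, trial = 1:2, onset_scan = c(2L, 30L),
                   onset_seconds = c(2L, 30L) * cfg$tr_seconds,
                   condition = "isolated")
  sched <- mdlhrf:::new_event_schedule(ev, cfg$tr_seconds)
  dat <- synthesize_bold(sched, truth, cfg, seed = 1)
  expect_message(trimmed <- discard_initial_volumes(dat, 4L), "dropped 1 event")
  expect_equal(nrow(trimmed$schedule), 1L)
  expect_equal(trimmed$schedule$onset_scan, 26L)
})

test_that("an all-zero HRF makes active and inactive voxels identical", {
  cfg <- noiseless_config()
  truth <- ground_truth(cfg, "young", hrf = rep(0, cfg$hrf_length_scans))
  sched <- generate_paradigm(cfg, seed = 4)
  dat <- synthesize_bold(sched, truth, cfg, seed = 4)
  expect_equal(dat$runs[[1]][1, ], dat$runs[[1]][cfg$n_active_voxels + 1L, ])
})
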