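test_that("trial differences subtract the first scan from the third", {
  expect_equal(trial_differences(rep(100, 20), c(0, 5, 10)), c(0, 0, 0))
  expect_equal(trial_differences(c(100, 101, 103), 0), 3)
  # noiseless generative model: isolated-trial differences equal the HRF peak
  cfg <- noiseless_config()
  truth <- ground_truth(cfg, "young")
  onsets <- c(5L, 25L, 45L)
  ev <- data.frame(run = 1L, trial = 1:3, onset_scan = onsets,
                   onset_seconds = onsets * cfg$tr_seconds,
                   condition = "isolated")
  sched <- mdlhrf:::new_event_schedule(ev, cfg$tr_seconds)
  dat <- synthesize_bold(sched, truth, cfg, seed = 1)
  d <- trial_differences(dat$runs[[1]][1, ], onsets)
  expect_equal(d, rep(max(truth$hrf) - truth$hrf[1], 3), tolerance = 1e-12)
  expect_warning(trial_differences(rep(0, 5), c(0, 4)), "truncated")
})

test_that("the one-sample t statistic follows its definition", {
  expect_equal(voxel_tstat(c(1, 2, 3, 4)), 2.5 / (sd(c(1, 2, 3, 4)) / 2))
  expect_equal(voxel_tstat(c(1, 2, 3, 4)), 3.873, tolerance = 1e-3)
  expect_equal(voxel_tstat(c(-1, 1, -2, 2)), 0)
  expect_identical(voxel_tstat(c(3, 3, 3, 3)), Inf)
  expect_identical(voxel_tstat(c(-3, -3, -3)), -Inf)
  expect_identical(voxel_tstat(c(0, 0, 0)), 0)
  expect_error(voxel_tstat(5), "at least 2")
})

test_that("the t map agrees with per-voxel computation", {
  cfg <- small_config()
  sim <- simulate_subject(cfg, "nondemented", seed = 2)
  tm <- tstat_map(sim$dataset)
  expect_s3_class(tm, "tstat_map")
  expect_equal(nrow(tm), 24L)
  v <- 3L
  d <- unlist(lapply(1:2, function(r) {
    trial_differences(sim$dataset$runs[[r]][v, ],
                      mdlhrf:::run_onsets(sim$dataset$schedule, r))
  }))
  expect_equal(tm$t[v], voxel_tstat(d))
  expect_equal(tm$n_trials[v], length(d))
})

test_that("top-voxel selection keeps the largest positive t values only", {
  tmap <- data.frame(voxel_id = sprintf("v%03d", 1:200),
                     t = c(seq(0.1, 10, length.out = 100), rep(-1, 100)))
  vs <- select_top_voxels(tmap, 32)
  expect_equal(nrow(vs), 32L)
  expect_true(all(vs$t > 0))
  expect_equal(vs$t, sort(tmap$t, decreasing = TRUE)[1:32])
  # guarantee: nothing excluded with larger positive t than anything kept
  expect_gte(min(vs$t), max(setdiff(tmap$t[tmap$t > 0], vs$t)))

  few <- data.frame(voxel_id = sprintf("v%03d", 1:30),
                    t = c(rep(2, 20), rep(-2, 10)))
  expect_warning(vs2 <- select_top_voxels(few, 32), "only 20")
  expect_equal(nrow(vs2), 20L)

  none <- data.frame(voxel_id = c("a", "b"), t = c(-1, 0))
  expect_warning(vs3 <- select_top_voxels(none, 32), "no voxel")
  expect_equal(nrow(vs3), 0L)
})

test_that("boundary ties resolve to the lower voxel id", {
  tmap <- data.frame(voxel_id = c("v05", "v01", "v03", "v02"),
                     t = c(1, 1, 2, 1))
  vs <- select_top_voxels(tmap, 2)
  expect_equal(vs$voxel_id, c("v03", "v01"))
})

test_that("overlap metrics match the identical/disjoint/8-shared fixtures", {
  a <- sprintf("v%03d", 1:32)
  expect_equal(voxel_overlap_metrics(a, a)$percent_new, 0)
  expect_equal(voxel_overlap_metrics(a, a)$percent_not_common, 0)
  b <- sprintf("v%03d", 33:64)
  expect_equal(voxel_overlap_metrics(a, b)$percent_new, 100)
  expect_equal(voxel_overlap_metrics(a, b)$percent_not_common, 100)
  c8 <- sprintf("v%03d", 25:56) # shares 25..32 with a: 8 voxels
  expect_equal(voxel_overlap_metrics(a, c8)$percent_new, 75)
  expect_warning(m <- voxel_overlap_metrics(a, character(0)), "empty")
  expect_true(is.na(m$percent_new))
})

test_that("noiseless selection returns exactly the active voxels", {
  cfg <- experiment_config(group_snr = c(young = Inf))
  sim <- simulate_subject(cfg, "young", seed = 3)
  vs <- select_top_voxels(tstat_map(sim$dataset), 32)
  expect_setequal(vs$voxel_id, sim$dataset$voxel_ids[sim$truth$active_mask])
})

test_that("top-32 purity is non-decreasing in SNR", {
  snrs <- c(0.2, 0.35, 0.52, 1.0)
  purity <- matrix(NA_real_, 40, length(snrs))
  seeds <- mdlhrf:::derive_seeds(71, 40)
  for (j in seq_along(snrs)) {
    cfg <- small_config(group_snr = c(young = snrs[j]))
    for (i in 1:40) {
      sim <- simulate_subject(cfg, "young", seed = seeds[i])
      vs <- suppressWarnings(select_top_voxels(tstat_map(sim$dataset), 12))
      purity[i, j] <- mean(vs$voxel_id %in%
                             sim$dataset$voxel_ids[sim$truth$active_mask])
    }
  }
  expect_true(all(diff(colMeans(purity)) >= 0))
})

test_that("denoising reshuffles the selected set more at low SNR", {
  pct_new <- function(snr, seeds) {
    cfg <- experiment_config(group_snr = c(g = snr))
    vapply(seeds, function(s) {
      sim <- simulate_subject(cfg, "g", seed = s)
      before <- select_top_voxels(tstat_map(sim$dataset), 32)
      after <- select_top_voxels(tstat_map(denoise_dataset(sim$dataset)), 32)
      voxel_overlap_metrics(before, after)$percent_new
    }, numeric(1))
  }
  seeds <- mdlhrf:::derive_seeds(72, 25)
  lo <- pct_new(0.35, seeds)
  hi <- pct_new(0.52, seeds)
  expect_gt(mean(lo), mean(hi))
})
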