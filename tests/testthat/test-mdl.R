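ref_coefs <- c(4, 2, 1, 1, 0.5, 0.5, 0.25, 0.25)

test_that("MDL costs match term-by-term evaluation of the published forms", {
  # n = 8, k = 2: S = 22.625, S_gamma = 20, residual = 2.625
  expect_equal(cmdl_cost(ref_coefs, 2),
               3 * log(2.625 / 6) + log(20 / 2) + 0.5 * log(12),
               tolerance = 1e-12)
  expect_equal(cmdl_cost(ref_coefs, 2), 1.0650, tolerance = 1e-4)
  expect_equal(rmdl_cost(ref_coefs, 2),
               3 * log(2.625 / 216) + log(20 / 8),
               tolerance = 1e-12)
  expect_equal(rmdl_cost(ref_coefs, 2), -12.314, tolerance = 1e-3)
})

test_that("crude and refined costs differ by the closed-form correction", {
  set.seed(21)
  coefs <- rnorm(64)
  n <- length(coefs)
  for (k in c(1, 5, 17, 40, mdl_kmax(n))) {
    corr <- ((n - k) / 2) * log((n - k)^2) + (k / 2) * log(k^2) +
      0.5 * log(k * (n - k))
    expect_equal(cmdl_cost(coefs, k) - rmdl_cost(coefs, k), corr,
                 tolerance = 1e-9)
  }
})

test_that("the argmin over k is invariant to rescaling the coefficients", {
  set.seed(22)
  coefs <- rnorm(128)
  for (cr in c("cmdl", "rmdl")) {
    k1 <- select_k(coefs, cr)$k
    k2 <- select_k(coefs * 37.5, cr)$k
    expect_identical(k1, k2)
  }
})

test_that("degenerate energies hit the -Inf sentinel", {
  # all signal energy inside gamma at k = 3: zero residual
  coefs <- c(3, 2, 1, 0, 0, 0, 0, 0)
  expect_identical(cmdl_cost(coefs, 3), -Inf)
  expect_identical(rmdl_cost(coefs, 3), -Inf)
  # a zero-residual k wins the argmin, smallest such k on ties
  expect_equal(select_k(coefs, "rmdl")$k, 3L)
})

test_that("the search range respects the strict k < 0.95 n bound", {
  expect_equal(mdl_kmax(8), 7L)     # 0.95 * 8 = 7.6
  expect_equal(mdl_kmax(128), 121L) # floor(121.6)
  expect_equal(mdl_kmax(20), 18L)   # 0.95 * 20 = 19 exactly: excluded
  curve <- mdl_cost_curve(rnorm(8), "cmdl")
  expect_equal(max(as.integer(names(curve))), 7L) # k = 8 never evaluated
})

test_that("select_k matches the brute-force oracle on random inputs", {
  set.seed(23)
  for (n in c(32L, 64L, 128L)) {
    for (i in 1:25) {
      coefs <- rnorm(n) * sample(c(1, 10), n, replace = TRUE)
      for (cr in c("cmdl", "rmdl")) {
        expect_identical(select_k(coefs, cr)$k,
                         as.integer(oracle_select_k(coefs, cr)))
      }
    }
  }
})

test_that("gamma holds the k largest magnitudes with deterministic ties", {
  coefs <- c(2, -2, 2, 1, 0.5, 0.25, 0.125, 0.0625)
  sel <- select_k(coefs, "rmdl")
  expect_equal(length(sel$gamma), sel$k)
  expect_lte(sel$S_gamma, sel$S_total)
  # duplicate magnitudes at the boundary resolve to lowest indices
  in_mag <- abs(coefs[sel$gamma])
  out_mag <- abs(coefs[-sel$gamma])
  expect_gte(min(in_mag), max(out_mag))
  if (min(in_mag) == max(out_mag)) {
    tied <- which(abs(coefs) == min(in_mag))
    expect_identical(intersect(tied, sel$gamma),
                     utils::head(tied, sum(in_mag == min(in_mag))))
  }
})

test_that("an all-zero coefficient vector returns the k = 0 sentinel", {
  expect_warning(sel <- select_k(rep(0, 16), "rmdl"), "undefined")
  expect_identical(sel$k, 0L)
  expect_identical(sel$gamma, integer(0))
})

test_that("denoising preserves a sparse noiseless signal", {
  set.seed(24)
  spec <- wavelet_spec()
  layout <- dwt_forward(rep(0, 128), spec)
  coefs <- rep(0, 128)
  coefs[c(3, 17, 40, 77, 100)] <- c(9, -7, 6, 5, -4) # 5-coefficient signal
  y <- dwt_inverse(layout, coefs)
  out <- denoise_series(y, spec, "rmdl")
  expect_lt(sqrt(mean((out - y)^2)) / sd(y), 1e-6)
})

test_that("denoising contracts energy and shrinks white noise", {
  set.seed(25)
  reduced <- logical(100)
  for (i in 1:100) {
    y <- rnorm(64)
    out <- suppressWarnings(denoise_series(y, criterion = "rmdl"))
    expect_lte(sum(out^2), sum(y^2) + 1e-10)
    reduced[i] <- sum(out^2) < sum(y^2)
  }
  expect_gt(mean(reduced), 0.95)
})

test_that("denoising a flat series returns it unchanged with a warning", {
  y <- rep(5, 32)
  expect_warning(out <- denoise_series(y), "unchanged")
  expect_equal(as.numeric(out), y)
  expect_identical(attr(out, "k"), 0L)
})

test_that("denoising improves mean squared error against the ground truth", {
  set.seed(26)
  spec <- wavelet_spec()
  for (snr in c(0.35, 0.52)) {
    mse_raw <- mse_dn <- numeric(100)
    cfg <- experiment_config(n_active_voxels = 1L, n_inactive_voxels = 1L,
                             group_snr = c(young = snr), n_runs = 1L)
    truth <- ground_truth(cfg, "young")
    for (i in 1:100) {
      sched <- generate_paradigm(cfg)
      dat <- synthesize_bold(sched, truth, cfg)
      clean <- synthesize_bold(sched, ground_truth(
        experiment_config(n_active_voxels = 1L, n_inactive_voxels = 1L,
                          group_snr = c(young = Inf), n_runs = 1L), "young"),
        cfg)
      y <- dat$runs[[1]][1, ]
      x <- clean$runs[[1]][1, ]
      out <- denoise_series(y, spec, "rmdl")
      mse_raw[i] <- mean((y - x)^2)
      mse_dn[i] <- mean((out - x)^2)
    }
    expect_lt(mean(mse_dn), mean(mse_raw))
  }
})

test_that("dataset denoising equals the per-series reference path", {
  cfg <- small_config()
  sim <- simulate_subject(cfg, "nondemented", seed = 31)
  dn <- denoise_dataset(sim$dataset, criterion = "rmdl")
  for (v in c(1L, 13L)) {
    ref <- denoise_series(sim$dataset$runs[[2]][v, ], criterion = "rmdl")
    expect_equal(unname(dn$runs[[2]][v, ]), as.numeric(ref), tolerance = 1e-12)
    expect_identical(attr(dn, "mdl_k")$k[attr(dn, "mdl_k")$run == 2][v],
                     attr(ref, "k"))
  }
})
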