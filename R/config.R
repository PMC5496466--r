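#' Experiment configuration for the event-related paradigm
#'
#' Bundles the acquisition and paradigm parameters that every stage of the
#' pipeline shares. The defaults reproduce a slow event-related sensory-motor
#' design: 4 runs of 128 whole-brain volumes at TR 2.68 s, 15 trials per run
#' (60 in total), each trial occupying an 8-scan (21.44 s) window, with paired
#' stimuli separated by 5.36 s (exactly 2 TR), and the first 4 volumes of each
#' run discarded for longitudinal magnetisation equilibration.
#'
#' Group signal-to-noise ratios are expressed as HRF peak amplitude divided by
#' noise standard deviation; the defaults (0.52 young, 0.35 elderly) encode
#' the well-documented SNR loss of BOLD data in older subjects.
#'
#' @param tr_seconds repetition time between volumes, seconds.
#' @param volumes_per_run volumes acquired per run (before discarding).
#' @param n_runs number of runs.
#' @param trials_per_run trials per run; paired stimuli count as one trial.
#' @param discard_initial volumes dropped from the start of each run.
#' @param pair_interval_seconds onset spacing of the two stimuli of a paired
#'   trial; must be an integer multiple of `tr_seconds`.
#' @param trial_window_scans scans reserved per trial (the trial duration).
#' @param hrf_length_scans length of the modelled HRF, in scans.
#' @param group_snr named vector mapping group label to peak-over-sigma SNR.
#'   `Inf` yields noiseless data.
#' @param n_active_voxels,n_inactive_voxels voxels with/without evoked signal
#'   in the simulated region of interest. The defaults (32 + 48) make the
#'   genuinely responsive voxels exactly fill the standard top-32 selection,
#'   mirroring reports that the selected voxels dominate the remainder's
#'   t-values; see the methods vignette.
#' @param noise_model `"white"` (i.i.d. Gaussian) or `"ar1"`.
#' @param ar_coef lag-1 autocorrelation used when `noise_model = "ar1"`.
#' @param drift_amplitude amplitude (signal units) of an optional slow cosine
#'   drift; 0 disables it.
#' @param drift_period_seconds period of the drift (>= 64 s).
#' @param baseline resting signal level, arbitrary scanner units.
#' @param stim_duration_seconds stimulus duration recorded in event files.
#'
#' @return An object of class `experiment_config` (a validated list).
#' @export
#' @examples
#' cfg <- experiment_config()
#' cfg$trial_window_scans * cfg$tr_seconds # 21.44 s trial window
experiment_config <- function(tr_seconds = 2.68,
                              volumes_per_run = 128L,
                              n_runs = 4L,
                              trials_per_run = 15L,
                              discard_initial = 4L,
                              pair_interval_seconds = 5.36,
                              trial_window_scans = 8L,
                              hrf_length_scans = 8L,
                              group_snr = c(young = 0.52,
                                            nondemented = 0.35,
                                            demented = 0.35),
                              n_active_voxels = 32L,
                              n_inactive_voxels = 48L,
                              noise_model = c("white", "ar1"),
                              ar_coef = 0.3,
                              drift_amplitude = 0,
                              drift_period_seconds = 128,
                              baseline = 100,
                              stim_duration_seconds = 1.5) {
  noise_model <- match.arg(noise_model)
  stop_if_not_scalar_number(tr_seconds, "tr_seconds")
  stop_if_not_scalar_number(volumes_per_run, "volumes_per_run", integerish = TRUE)
  stop_if_not_scalar_number(n_runs, "n_runs", integerish = TRUE)
  stop_if_not_scalar_number(trials_per_run, "trials_per_run", integerish = TRUE)
  stop_if_not_scalar_number(discard_initial, "discard_initial",
                            integerish = TRUE, zero_ok = TRUE)
  stop_if_not_scalar_number(pair_interval_seconds, "pair_interval_seconds")
  stop_if_not_scalar_number(trial_window_scans, "trial_window_scans", integerish = TRUE)
  stop_if_not_scalar_number(hrf_length_scans, "hrf_length_scans", integerish = TRUE)
  stop_if_not_scalar_number(n_active_voxels, "n_active_voxels", integerish = TRUE)
  stop_if_not_scalar_number(n_inactive_voxels, "n_inactive_voxels",
                            integerish = TRUE, zero_ok = TRUE)
  stop_if_not_scalar_number(drift_amplitude, "drift_amplitude", zero_ok = TRUE)
  stop_if_not_scalar_number(drift_period_seconds, "drift_period_seconds")
  stop_if_not_scalar_number(baseline, "baseline")

  if (!is.numeric(group_snr) || is.null(names(group_snr)) ||
      any(!nzchar(names(group_snr))) || any(group_snr <= 0)) {
    stop("'group_snr' must be a named vector of positive SNR values", call. = FALSE)
  }
  if (discard_initial >= volumes_per_run) {
    stop("'discard_initial' must be smaller than 'volumes_per_run'", call. = FALSE)
  }
  ratio <- pair_interval_seconds / tr_seconds
  if (abs(ratio - round(ratio)) > 1e-8) {
    stop("'pair_interval_seconds' must be an integer multiple of 'tr_seconds'",
         call. = FALSE)
  }
  if (drift_period_seconds < 64) {
    stop("'drift_period_seconds' must be at least 64 s (slow drift only)",
         call. = FALSE)
  }

  cfg <- list(
    tr_seconds = tr_seconds,
    volumes_per_run = as.integer(volumes_per_run),
    n_runs = as.integer(n_runs),
    trials_per_run = as.integer(trials_per_run),
    discard_initial = as.integer(discard_initial),
    pair_interval_seconds = pair_interval_seconds,
    pair_interval_scans = as.integer(round(ratio)),
    trial_window_scans = as.integer(trial_window_scans),
    hrf_length_scans = as.integer(hrf_length_scans),
    group_snr = group_snr,
    n_active_voxels = as.integer(n_active_voxels),
    n_inactive_voxels = as.integer(n_inactive_voxels),
    noise_model = noise_model,
    ar_coef = ar_coef,
    drift_amplitude = drift_amplitude,
    drift_period_seconds = drift_period_seconds,
    baseline = baseline,
    stim_duration_seconds = stim_duration_seconds
  )
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Event-related fMRI experiment configuration\n")
  cat(sprintf("  %d runs x %d volumes, TR %.3g s (%d discarded per run)\n",
              x$n_runs, x$volumes_per_run, x$tr_seconds, x$discard_initial))
  cat(sprintf("  %d trials/run, %d-scan trial window (%.4g s), pair spacing %.4g s\n",
              x$trials_per_run, x$trial_window_scans,
              x$trial_window_scans * x$tr_seconds, x$pair_interval_seconds))
  cat(sprintf("  voxels: %d active + %d inactive; noise: %s\n",
              x$n_active_voxels, x$n_inactive_voxels, x$noise_model))
  cat("  group SNR:",
      paste(sprintf("%s=%.3g", names(x$group_snr), x$group_snr), collapse = ", "),
      "\n")
  invisible(x)
}

#' Canonical ground-truth HRF sampled on the scan grid
#'
#' A double-gamma haemodynamic response sampled every `tr_seconds` seconds,
#' rescaled to unit peak. At TR 2.68 s the response is exactly zero at the
#' onset scan and peaks at the third post-onset scan (lag 2, 5.36 s),
#' consistent with the 4-6 s peak latency of the adult HRF.
#'
#' @param length_scans number of samples (default 8).
#' @param tr_seconds sampling interval in seconds.
#' @param peak peak amplitude in signal units (default 1).
#' @return Numeric vector of `length_scans` amplitudes.
#' @export
#' @examples
#' h <- default_hrf()
#' which.max(h) - 1L # peak at lag 2
default_hrf <- function(length_scans = 8L, tr_seconds = 2.68, peak = 1) {
  t <- (seq_len(length_scans) - 1) * tr_seconds
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h) * peak
  h[1] <- 0 # dgamma(0, shape > 1) is 0; make it exact against roundoff
  h
}

#' Ground truth for a simulated subject
#'
#' @param config an [experiment_config()].
#' @param group group label; must name an entry of `config$group_snr`.
#' @param hrf ground-truth HRF in signal units (length `hrf_length_scans`);
#'   must be 0 at lag 0 and peak at lag 2.
#' @param amplitude multiplier applied to `hrf` (used e.g. to impose a genuine
#'   group difference in power studies).
#' @param baseline resting level per voxel (scalar recycled, or one per voxel).
#' @return Object of class `ground_truth` with fields `hrf`, `baseline`,
#'   `active_mask`, `noise_sd`, `group`.
#' @export
ground_truth <- function(config, group = "young",
                         hrf = default_hrf(config$hrf_length_scans,
                                           config$tr_seconds),
                         amplitude = 1,
                         baseline = config$baseline) {
  stopifnot(inherits(config, "experiment_config"))
  if (!group %in% names(config$group_snr)) {
    stop(sprintf("unknown group '%s'; configured groups: %s", group,
                 paste(names(config$group_snr), collapse = ", ")), call. = FALSE)
  }
  if (length(hrf) != config$hrf_length_scans) {
    stop("'hrf' must have length hrf_length_scans", call. = FALSE)
  }
  if (hrf[1] != 0) {
    stop("'hrf' must be 0 at lag 0 (response has not risen at the onset scan)",
         call. = FALSE)
  }
  hrf <- hrf * amplitude
  snr <- unname(config$group_snr[[group]])
  noise_sd <- if (is.infinite(snr)) 0 else max(hrf) / snr
  nvox <- config$n_active_voxels + config$n_inactive_voxels
  baseline <- rep_len(baseline, nvox)
  truth <- list(
    hrf = hrf,
    baseline = baseline,
    active_mask = c(rep(TRUE, config$n_active_voxels),
                    rep(FALSE, config$n_inactive_voxels)),
    noise_sd = noise_sd,
    group = group
  )
  class(truth) <- "ground_truth"
  truth
}
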