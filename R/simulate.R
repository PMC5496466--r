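new_bold_dataset <- function(runs, tr_seconds, voxel_ids, group_label,
                             schedule, discarded = 0L) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  nv <- unique(vapply(runs, nrow, integer(1)))
  nt <- unique(vapply(runs, ncol, integer(1)))
  if (length(nv) != 1L || length(nt) != 1L) {
    stop("all runs must share voxel count and time length", call. = FALSE)
  }
  if (length(voxel_ids) != nv) {
    stop("voxel_ids length must match the run matrices", call. = FALSE)
  }
  runs <- lapply(runs, function(m) { rownames(m) <- voxel_ids; m })
  structure(list(runs = runs,
                 tr_seconds = tr_seconds,
                 voxel_ids = voxel_ids,
                 group_label = group_label,
                 schedule = schedule,
                 discarded = as.integer(discarded)),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("BOLD dataset: %d voxels x %d scans x %d run(s), TR %.3g s, group '%s'\n",
              nrow(x$runs[[1]]), ncol(x$runs[[1]]), length(x$runs),
              x$tr_seconds, x$group_label))
  if (x$discarded > 0) {
    cat(sprintf("  (%d initial volumes already discarded per run)\n", x$discarded))
  }
  invisible(x)
}

n_voxels <- function(dataset) nrow(dataset$runs[[1]])
n_scans_per_run <- function(dataset) ncol(dataset$runs[[1]])

#' Synthesize noisy BOLD time series from a schedule and ground truth
#'
#' Each run is built as `baseline + (impulse train convolved with hrf) +
#' drift + noise`. Active voxels (per `truth$active_mask`) carry the evoked
#' response; inactive voxels carry baseline, drift and noise only. Both
#' impulses of a paired trial enter the impulse train with unit amplitude:
#' the HRF is modelled as time-invariant, so overlapping responses add
#' linearly. Noise is white Gaussian or AR(1) with stationary standard
#' deviation `truth$noise_sd`; the optional drift is a slow cosine with a
#' voxel-specific random phase.
#'
#' @param schedule an `event_schedule` from [generate_paradigm()].
#' @param truth a [ground_truth()].
#' @param config the [experiment_config()] used to build both.
#' @param seed integer seed for reproducible noise; `NULL` uses the current
#'   RNG stream.
#' @return A `bold_dataset` with `config$n_runs` voxel-by-time matrices of
#'   `volumes_per_run` scans each (nothing discarded yet).
#' @export
synthesize_bold <- function(schedule, truth, config, seed = NULL) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(truth, "ground_truth"),
            inherits(config, "experiment_config"))
  if (!is.numeric(truth$noise_sd) || truth$noise_sd < 0) {
    stop("'noise_sd' must be non-negative", call. = FALSE)
  }
  nvox <- length(truth$active_mask)
  Tn <- config$volumes_per_run
  L <- length(truth$hrf)
  if (any(schedule$onset_scan < 0 | schedule$onset_scan >= Tn)) {
    stop("schedule contains onsets outside the run", call. = FALSE)
  }
  with_seed(seed, {
    runs <- lapply(seq_len(config$n_runs), function(r) {
      resp <- rep(0, Tn)
      for (o in run_onsets(schedule, r)) {
        j <- 0:min(L - 1L, Tn - 1L - o)
        resp[o + j + 1L] <- resp[o + j + 1L] + truth$hrf[j + 1L]
      }
      Y <- matrix(truth$baseline, nvox, Tn)
      if (any(truth$active_mask)) {
        Y[truth$active_mask, ] <- Y[truth$active_mask, ] +
          matrix(resp, sum(truth$active_mask), Tn, byrow = TRUE)
      }
      if (config$drift_amplitude > 0) {
        phase <- stats::runif(nvox, 0, 2 * pi)
        tsec <- (0:(Tn - 1L)) * config$tr_seconds
        Y <- Y + config$drift_amplitude *
          cos(outer(phase, 2 * pi * tsec / config$drift_period_seconds, `+`))
      }
      if (truth$noise_sd > 0) {
        if (config$noise_model == "white") {
          Y <- Y + matrix(stats::rnorm(nvox * Tn, sd = truth$noise_sd), nvox, Tn)
        } else {
          innov <- matrix(stats::rnorm(nvox * Tn), nvox, Tn)
          scale <- truth$noise_sd * sqrt(1 - config$ar_coef^2)
          E <- t(apply(innov, 1, function(e) {
            as.numeric(stats::filter(e, config$ar_coef, method = "recursive"))
          }))
          Y <- Y + E * scale
        }
      }
      Y
    })
    new_bold_dataset(runs, config$tr_seconds,
                     voxel_ids = sprintf("v%03d", seq_len(nvox)),
                     group_label = truth$group,
                     schedule = schedule)
  })
}

#' Discard initial volumes of every run
#'
#' Drops the first `discard` volumes of each run (longitudinal magnetisation
#' equilibration scans) and shifts all event onsets accordingly. Events whose
#' trial windows would start before the new time origin are dropped with a
#' message.
#'
#' @param dataset a `bold_dataset`.
#' @param discard number of volumes to drop per run, or an
#'   [experiment_config()] whose `discard_initial` is used.
#' @return The trimmed `bold_dataset`.
#' @export
discard_initial_volumes <- function(dataset, discard = 4L) {
  stopifnot(inherits(dataset, "bold_dataset"))
  if (inherits(discard, "experiment_config")) discard <- discard$discard_initial
  discard <- as.integer(discard)
  if (discard == 0L) return(dataset)
  Tn <- n_scans_per_run(dataset)
  if (discard < 0L || discard >= Tn) {
    stop("'discard' must be in [0, scans per run)", call. = FALSE)
  }
  runs <- lapply(dataset$runs, function(m) m[, -(seq_len(discard)), drop = FALSE])
  sched <- as.data.frame(dataset$schedule)
  sched$onset_scan <- sched$onset_scan - discard
  dropped <- sched$onset_scan < 0L
  if (any(dropped)) {
    message(sprintf("discard_initial_volumes: dropped %d event(s) starting before the new origin",
                    sum(dropped)))
    sched <- sched[!dropped, , drop = FALSE]
  }
  sched$onset_seconds <- sched$onset_scan * dataset$tr_seconds
  new_bold_dataset(runs, dataset$tr_seconds, dataset$voxel_ids,
                   dataset$group_label,
                   new_event_schedule(sched, dataset$tr_seconds),
                   discarded = dataset$discarded + discard)
}

#' Simulate one subject end to end
#'
#' Convenience wrapper: generates a paradigm, draws ground truth for the
#' requested group, synthesizes the BOLD data and discards the initial
#' volumes, all under one seed.
#'
#' @inheritParams ground_truth
#' @param seed integer seed controlling both paradigm and noise.
#' @param discard whether to drop the initial volumes (default TRUE).
#' @return List with elements `dataset` (post-discard `bold_dataset`),
#'   `truth`, and `config`.
#' @export
simulate_subject <- function(config, group = "young", seed = NULL,
                             hrf = default_hrf(config$hrf_length_scans,
                                               config$tr_seconds),
                             amplitude = 1, discard = TRUE) {
  truth <- ground_truth(config, group, hrf = hrf, amplitude = amplitude)
  with_seed(seed, {
    sched <- generate_paradigm(config)
    dat <- synthesize_bold(sched, truth, config)
    if (discard) dat <- discard_initial_volumes(dat, config$discard_initial)
    list(dataset = dat, truth = truth, config = config)
  })
}
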