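new_event_schedule <- function(events, tr_seconds) {
  events <- as.data.frame(events)
  needed <- c("run", "trial", "onset_scan", "onset_seconds", "condition")
  stopifnot(all(needed %in% names(events)))
  events <- events[order(events$run, events$onset_scan), needed, drop = FALSE]
  rownames(events) <- NULL
  structure(events,
            tr_seconds = tr_seconds,
            class = c("event_schedule", "data.frame"))
}

#' Generate a pseudo-random event-related paradigm
#'
#' Lays out `trials_per_run` non-overlapping trial windows of
#' `trial_window_scans` scans per run, starting after the discarded initial
#' volumes, and pseudo-randomly intermixes two trial conditions: an isolated
#' stimulus, and a pair of stimuli whose onsets are `pair_interval_seconds`
#' apart. Any slack scans left over in a run are scattered as random gaps
#' between trial windows. Onsets are locked to the scan grid, so
#' `onset_seconds = onset_scan * tr_seconds` exactly (scan indices are
#' 0-based; runs are numbered from 1).
#'
#' With the default configuration this yields 60 trials across 4 runs, where
#' a paired trial counts as one trial contributing two events
#' (`paired_first`, `paired_second`).
#'
#' @param config an [experiment_config()].
#' @param seed integer seed; identical seeds give identical schedules.
#'   `NULL` draws from the current RNG stream.
#' @return An `event_schedule`: a data frame with columns `run`, `trial`,
#'   `onset_scan` (0-based), `onset_seconds`, `condition`.
#' @export
#' @examples
#' sched <- generate_paradigm(experiment_config(), seed = 1)
#' length(unique(sched$trial)) # 60 trials
generate_paradigm <- function(config, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  usable <- config$volumes_per_run - config$discard_initial
  need <- config$trials_per_run * config$trial_window_scans
  if (need > usable) {
    stop(sprintf(paste0("cannot place %d trials of %d scans in %d usable ",
                        "volumes per run"),
                 config$trials_per_run, config$trial_window_scans, usable),
         call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    trial_id <- 0L
    for (r in seq_len(config$n_runs)) {
      slack <- usable - need
      gaps <- if (slack > 0) {
        as.vector(stats::rmultinom(1, slack,
                                   rep(1, config$trials_per_run + 1L)))[
                                     seq_len(config$trials_per_run)]
      } else {
        rep(0L, config$trials_per_run)
      }
      starts <- config$discard_initial + cumsum(gaps) +
        (seq_len(config$trials_per_run) - 1L) * config$trial_window_scans
      n_paired <- config$trials_per_run %/% 2L
      cond <- sample(rep(c("paired", "isolated"),
                         c(n_paired, config$trials_per_run - n_paired)))
      for (i in seq_len(config$trials_per_run)) {
        trial_id <- trial_id + 1L
        if (cond[i] == "isolated") {
          rows[[length(rows) + 1L]] <- data.frame(
            run = r, trial = trial_id, onset_scan = starts[i],
            condition = "isolated", stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            run = r, trial = trial_id,
            onset_scan = c(starts[i], starts[i] + config$pair_interval_scans),
            condition = c("paired_first", "paired_second"),
            stringsAsFactors = FALSE)
        }
      }
    }
    ev <- do.call(rbind, rows)
    ev$onset_seconds <- ev$onset_scan * config$tr_seconds
    new_event_schedule(ev, config$tr_seconds)
  })
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("Event schedule: %d events / %d trials across %d run(s), TR %.3g s\n",
              nrow(x), length(unique(x$trial)), length(unique(x$run)),
              attr(x, "tr_seconds")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more events\n", nrow(x) - 6L))
  invisible(x)
}

# Onsets (0-based scans) of every event in one run.
run_onsets <- function(schedule, run) {
  schedule$onset_scan[schedule$run == run]
}
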