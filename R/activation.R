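#' Per-trial scan differences used for activation detection
#'
#' For each trial onset, returns the signal at the third scan of the trial
#' window minus the first (0-based lags 2 and 0 from the onset). At TR 2.68 s
#' lag 2 is 5.36 s post-onset, where the haemodynamic response is near its
#' 4-6 s peak, so the difference isolates the evoked response against the
#' pre-rise baseline scan.
#'
#' @param series numeric vector (one voxel's time series within one run).
#' @param onsets 0-based onset scans.
#' @param peak_lag,base_lag 0-based lags of the two scans (defaults 2 and 0).
#' @return Numeric vector, one difference per trial whose window fits;
#'   truncated windows are dropped with a warning.
#' @export
#' @examples
#' trial_differences(c(100, 101, 103, 102), onsets = 0) # 3
trial_differences <- function(series, onsets, peak_lag = 2L, base_lag = 0L) {
  stopifnot(is.numeric(series), peak_lag >= base_lag)
  onsets <- as.integer(onsets)
  ok <- onsets >= 0L & (onsets + peak_lag) < length(series)
  if (any(!ok)) {
    warning(sprintf("dropping %d trial(s) whose difference window is truncated",
                    sum(!ok)))
    onsets <- onsets[ok]
  }
  series[onsets + peak_lag + 1L] - series[onsets + base_lag + 1L]
}

#' One-sample t statistic over trial differences
#'
#' `t = mean(d) / (sd(d) / sqrt(m))` with the `m - 1` denominator in the
#' standard deviation. Zero variance with a nonzero mean yields the `+Inf` /
#' `-Inf` sentinel; zero variance and zero mean yield 0.
#'
#' @param differences numeric vector of per-trial differences (length >= 2).
#' @return The t statistic.
#' @export
#' @examples
#' voxel_tstat(c(1, 2, 3, 4)) # ~3.873
voxel_tstat <- function(differences) {
  m <- length(differences)
  if (m < 2L) stop("need at least 2 trials for a t statistic", call. = FALSE)
  mu <- mean(differences)
  s <- stats::sd(differences)
  if (s == 0) {
    return(if (mu == 0) 0 else sign(mu) * Inf)
  }
  mu / (s / sqrt(m))
}

#' Voxelwise t-statistic map for a dataset
#'
#' Computes the scan-difference t statistic per voxel, pooling trial
#' differences across all runs and all events (isolated and both onsets of a
#' paired trial contribute).
#'
#' @param dataset a `bold_dataset` (its schedule supplies the onsets).
#' @inheritParams trial_differences
#' @return A data frame of class `tstat_map` with columns `voxel_id`, `t`,
#'   `n_trials`.
#' @export
tstat_map <- function(dataset, peak_lag = 2L, base_lag = 0L) {
  stopifnot(inherits(dataset, "bold_dataset"))
  Tn <- n_scans_per_run(dataset)
  diffs <- list()
  for (r in seq_along(dataset$runs)) {
    on <- run_onsets(dataset$schedule, r)
    on <- on[on >= 0L & (on + peak_lag) < Tn]
    if (!length(on)) next
    Y <- dataset$runs[[r]]
    diffs[[length(diffs) + 1L]] <-
      Y[, on + peak_lag + 1L, drop = FALSE] - Y[, on + base_lag + 1L, drop = FALSE]
  }
  if (!length(diffs)) stop("no usable trials in any run", call. = FALSE)
  D <- do.call(cbind, diffs)
  m <- ncol(D)
  mu <- rowMeans(D)
  s <- sqrt(rowSums((D - mu)^2) / (m - 1))
  t <- ifelse(s == 0, ifelse(mu == 0, 0, sign(mu) * Inf), mu / (s / sqrt(m)))
  structure(data.frame(voxel_id = dataset$voxel_ids, t = t, n_trials = m,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("tstat_map", "data.frame"))
}

#' Select the top activated voxels by positive t value
#'
#' Keeps the `n_select` voxels with the largest strictly positive t values
#' (rank selection realises a per-subject threshold implicitly). Voxels with
#' negative or zero t -- deactivating voxels -- are never included. Ties at
#' the selection boundary break towards the lower `voxel_id`.
#'
#' @param tmap a [tstat_map()] result (or data frame with `voxel_id`, `t`).
#' @param n_select maximum number of voxels to keep (default 32).
#' @return A data frame of class `voxel_set` with columns `voxel_id`, `t`,
#'   `rank`, ordered by decreasing t. Fewer than `n_select` rows (with a
#'   warning) when fewer voxels have positive t; empty when none do.
#' @export
select_top_voxels <- function(tmap, n_select = 32L) {
  stopifnot(is.data.frame(tmap), nrow(tmap) > 0L)
  pos <- tmap[tmap$t > 0, , drop = FALSE]
  if (nrow(pos) == 0L) {
    warning("no voxel has a positive t value; returning an empty set")
  } else if (nrow(pos) < n_select) {
    warning(sprintf("only %d voxel(s) have positive t (requested %d)",
                    nrow(pos), n_select))
  }
  pos <- pos[order(-pos$t, pos$voxel_id), , drop = FALSE]
  pos <- utils::head(pos, n_select)
  out <- data.frame(voxel_id = pos$voxel_id, t = pos$t,
                    rank = seq_len(nrow(pos)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("voxel_set", "data.frame")
  out
}

#' Overlap change between two top-voxel sets
#'
#' Quantifies how much the selected activation set changes between two
#' analysis states (e.g. before and after MDL denoising). The primary metric
#' is the percentage of the post-state set that is new, i.e. absent from the
#' pre-state set; a symmetric "not common" variant (symmetric difference over
#' union) is reported alongside, since either convention appears in practice.
#'
#' @param set_before,set_after `voxel_set`s (or vectors of voxel ids).
#' @return List with `percent_new` (100 * |after \ before| / |after|),
#'   `percent_not_common` (100 * |sym. difference| / |union|), and the raw
#'   counts. `percent_new` is `NA` (with a warning) when `set_after` is empty.
#' @export
#' @examples
#' voxel_overlap_metrics(paste0("v", 1:32), paste0("v", 25:56))$percent_new # 75
voxel_overlap_metrics <- function(set_before, set_after) {
  ids <- function(x) if (is.data.frame(x)) x$voxel_id else as.character(x)
  b <- unique(ids(set_before))
  a <- unique(ids(set_after))
  if (length(a) == 0L) {
    warning("'set_after' is empty; percent_new is undefined")
    pct_new <- NA_real_
  } else {
    pct_new <- 100 * length(setdiff(a, b)) / length(a)
  }
  uni <- union(a, b)
  pct_nc <- if (length(uni) == 0L) NA_real_ else {
    100 * (length(uni) - length(intersect(a, b))) / length(uni)
  }
  list(percent_new = pct_new,
       percent_not_common = pct_nc,
       n_before = length(b), n_after = length(a),
       n_common = length(intersect(a, b)))
}
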