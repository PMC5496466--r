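new_hrf_curve <- function(samples, tr_seconds, method,
                          baseline_estimate = NA_real_, raw = NULL,
                          flagged = FALSE) {
  structure(list(samples = as.numeric(samples),
                 lag_seconds = (seq_along(samples) - 1) * tr_seconds,
                 method = method,
                 baseline_estimate = baseline_estimate,
                 raw = raw,
                 flagged = flagged),
            class = "hrf_curve")
}

#' @export
print.hrf_curve <- function(x, ...) {
  cat(sprintf("HRF curve (%s), %d lags, percent signal change%s\n",
              x$method, length(x$samples), if (x$flagged) " [flagged]" else ""))
  print(round(stats::setNames(x$samples, sprintf("%.2fs", x$lag_seconds)), 4))
  invisible(x)
}

#' HRF estimation by epoch averaging
#'
#' Averages the `L`-scan epochs following each onset, then normalises to
#' percent signal change about the first epoch scan:
#' `100 * (mean[j] - mean[0]) / mean[0]`. When responses to nearby events
#' overlap (paired trials), later epochs are contaminated by the neighbouring
#' response, which is the known bias of this estimator.
#'
#' @param series numeric vector (one run's series, or runs handled upstream).
#' @param onsets 0-based onset scans.
#' @param L epoch length in scans (default 8).
#' @param tr_seconds sampling interval, used for the lag axis.
#' @return An `hrf_curve` (method `"averaging"`); epochs running off the end
#'   of the series are dropped with a warning, and a non-positive baseline
#'   scan flags the curve.
#' @export
#' @examples
#' epoch_average_hrf(c(100, 101, 103, 102, 101, 100, 100, 100), 0)$samples
epoch_average_hrf <- function(series, onsets, L = 8L, tr_seconds = 2.68) {
  onsets <- as.integer(onsets)
  ok <- onsets >= 0L & (onsets + L) <= length(series)
  if (any(!ok)) {
    warning(sprintf("dropping %d trial(s) whose %d-scan epoch is truncated",
                    sum(!ok), L))
    onsets <- onsets[ok]
  }
  if (!length(onsets)) stop("no usable epochs", call. = FALSE)
  ep <- vapply(onsets, function(o) series[o + seq_len(L)], numeric(L))
  m <- rowMeans(ep)
  flagged <- m[1] <= 0
  if (flagged) {
    warning("baseline scan of the mean epoch is non-positive; percent change undefined")
    samples <- rep(NA_real_, L)
  } else {
    samples <- 100 * (m - m[1]) / m[1]
  }
  new_hrf_curve(samples, tr_seconds, "averaging",
                raw = list(mean_epoch = m, n_trials = length(onsets)),
                flagged = flagged)
}

#' Finite-impulse-response design matrix with baseline regressor
#'
#' Builds the `T x (L + 1)` stick design: column `j` (`j = 0..L-1`) is 1 at
#' scan `onset + j` for every onset (clipped at the series end), and the last
#' column is identically 1 to estimate the baseline as a regressor. With
#' `L = 8` the baseline is the ninth column.
#'
#' @param onsets 0-based onset scans (all `< T`).
#' @param T_scans series length in scans.
#' @param L HRF length in scans (default 8).
#' @return `T_scans x (L+1)` numeric 0/1 matrix of class `design_matrix`
#'   (plain matrix with attributes `L` and `onsets`).
#' @export
#' @examples
#' X <- build_design_matrix(c(2, 10), T_scans = 20)
#' dim(X) # 20 x 9
build_design_matrix <- function(onsets, T_scans, L = 8L) {
  onsets <- as.integer(onsets)
  if (!length(onsets)) stop("empty onset list", call. = FALSE)
  if (any(onsets < 0L | onsets >= T_scans)) {
    stop("all onsets must lie in [0, T_scans)", call. = FALSE)
  }
  X <- matrix(0, T_scans, L + 1L)
  for (o in onsets) {
    j <- 0:min(L - 1L, T_scans - 1L - o) # clip at the run end
    X[cbind(o + j + 1L, j + 1L)] <- 1
  }
  X[, L + 1L] <- 1
  structure(X, L = as.integer(L), onsets = onsets,
            class = c("design_matrix", class(X)))
}

# Stacked multi-run design: shared L HRF columns, one baseline column per
# run (block placement), so a single HRF is estimated across runs while each
# run keeps its own baseline level.
subject_design <- function(schedule, T_scans, n_runs, L = 8L) {
  total <- T_scans * n_runs
  X <- matrix(0, total, L + n_runs)
  for (r in seq_len(n_runs)) {
    rows <- (r - 1L) * T_scans + seq_len(T_scans)
    on <- run_onsets(schedule, r)
    if (length(on)) {
      Xr <- build_design_matrix(on, T_scans, L)
      X[rows, seq_len(L)] <- Xr[, seq_len(L)]
    }
    X[rows, L + r] <- 1
  }
  structure(X, L = as.integer(L), n_runs = as.integer(n_runs),
            class = c("design_matrix", class(X)))
}

#' HRF estimation by FIR deconvolution
#'
#' Solves `[h; b] = pinv(X) %*% y` where `X` is the FIR design with baseline
#' column(s) and `pinv` the Moore-Penrose pseudo-inverse (SVD, relative
#' singular-value cutoff 1e-10). The estimated response is reported in
#' percent signal change about the estimated baseline,
#' `100 * h[j] / mean(b)`; the raw `h` and baseline(s) are retained in the
#' result for users preferring additive correction.
#'
#' @param series numeric vector, length `nrow(design)`.
#' @param design a [build_design_matrix()] or multi-run design.
#' @param tr_seconds sampling interval, for the lag axis.
#' @return An `hrf_curve` (method `"deconvolution"`) with
#'   `baseline_estimate` (mean of the per-run baselines) and raw estimates in
#'   `$raw`. A rank-deficient design triggers a conditioning warning and the
#'   minimum-norm solution; a non-positive baseline flags the curve.
#' @export
deconvolve_hrf <- function(series, design, tr_seconds = 2.68) {
  stopifnot(is.numeric(series), nrow(design) == length(series))
  L <- attr(design, "L")
  Xp <- pseudo_inverse(unclass(design))
  if (attr(Xp, "rank") < ncol(design)) {
    warning(sprintf("rank-deficient design (rank %d of %d columns, condition %.3g); minimum-norm solution returned",
                    attr(Xp, "rank"), ncol(design), attr(Xp, "condition")))
  }
  coef <- as.numeric(Xp %*% series)
  h <- coef[seq_len(L)]
  b <- coef[(L + 1L):length(coef)]
  bmean <- mean(b)
  flagged <- !is.finite(bmean) || bmean <= 0
  samples <- if (flagged) rep(NA_real_, L) else 100 * h / bmean
  if (flagged) {
    warning("estimated baseline is non-positive; percent change undefined")
  }
  new_hrf_curve(samples, tr_seconds, "deconvolution",
                baseline_estimate = bmean,
                raw = list(h = h, baselines = b,
                           condition = attr(Xp, "condition")),
                flagged = flagged)
}

# Onsets usable for epoch averaging, per run, optionally isolated trials only.
averaging_onsets <- function(schedule, run, isolated_only = FALSE) {
  s <- schedule[schedule$run == run, , drop = FALSE]
  if (isolated_only) s <- s[s$condition == "isolated", , drop = FALSE]
  s$onset_scan
}

#' Mean ROI HRF across selected voxels
#'
#' Estimates a per-voxel HRF curve by the chosen method and averages across
#' the voxels of the set; the standard error of the mean (per lag) is the
#' across-voxel standard deviation divided by the square root of the voxel
#' count. For `"averaging"`, epochs are pooled across runs per voxel; for
#' `"deconvolution"`, runs are deconvolved jointly with one shared HRF and
#' per-run baseline regressors.
#'
#' @param dataset a `bold_dataset`.
#' @param voxels a `voxel_set` (or vector of voxel ids).
#' @param method `"deconvolution"` or `"averaging"`.
#' @param L HRF length in scans.
#' @param isolated_only for averaging: use isolated trials only (default
#'   FALSE, all events contribute).
#' @return List with `curve` (the mean `hrf_curve`), `sem` (length-`L`
#'   vector), `per_voxel` (voxel-by-lag matrix of percent-change curves),
#'   `n_used`, `n_excluded` (voxels flagged and dropped from the mean).
#' @export
mean_roi_hrf <- function(dataset, voxels,
                         method = c("deconvolution", "averaging"),
                         L = 8L, isolated_only = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "bold_dataset"))
  ids <- if (is.data.frame(voxels)) voxels$voxel_id else as.character(voxels)
  if (!length(ids)) stop("'voxels' must be non-empty", call. = FALSE)
  idx <- match(ids, dataset$voxel_ids)
  if (anyNA(idx)) stop("unknown voxel ids in 'voxels'", call. = FALSE)
  Tn <- n_scans_per_run(dataset)
  R <- length(dataset$runs)

  if (method == "deconvolution") {
    X <- subject_design(dataset$schedule, Tn, R, L)
    Xp <- pseudo_inverse(unclass(X))
    Y <- do.call(cbind, dataset$runs)[idx, , drop = FALSE]
    coefs <- Xp %*% t(Y) # (L + R) x n_voxels
    h <- coefs[seq_len(L), , drop = FALSE]
    b <- colMeans(coefs[(L + 1L):(L + R), , drop = FALSE])
    ok <- is.finite(b) & b > 0
    curves <- t(100 * sweep(h, 2, b, `/`))
  } else {
    curves <- matrix(NA_real_, length(idx), L)
    ok <- rep(TRUE, length(idx))
    epochs_of <- function(v) {
      eps <- list()
      for (r in seq_len(R)) {
        on <- averaging_onsets(dataset$schedule, r, isolated_only)
        on <- on[on >= 0L & (on + L) <= Tn]
        if (!length(on)) next
        y <- dataset$runs[[r]][v, ]
        eps[[length(eps) + 1L]] <- vapply(on, function(o) y[o + seq_len(L)],
                                          numeric(L))
      }
      do.call(cbind, eps)
    }
    for (i in seq_along(idx)) {
      ep <- epochs_of(idx[i])
      if (is.null(ep)) { ok[i] <- FALSE; next }
      m <- rowMeans(ep)
      if (m[1] <= 0) { ok[i] <- FALSE; next }
      curves[i, ] <- 100 * (m - m[1]) / m[1]
    }
  }

  if (!any(ok)) stop("all voxels flagged; no mean curve available", call. = FALSE)
  if (any(!ok)) {
    warning(sprintf("excluding %d flagged voxel(s) from the ROI mean", sum(!ok)))
  }
  cu <- curves[ok, , drop = FALSE]
  mean_curve <- colMeans(cu)
  sem <- apply(cu, 2, stats::sd) / sqrt(nrow(cu))
  rownames(curves) <- ids
  list(curve = new_hrf_curve(mean_curve, dataset$tr_seconds, method),
       sem = sem,
       per_voxel = curves,
       n_used = sum(ok),
       n_excluded = sum(!ok))
}
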