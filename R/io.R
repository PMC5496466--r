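#' Write an event schedule as tab-separated text
#'
#' BIDS-events dialect: header `onset`, `duration`, `trial_type` (in that
#' order), plus `onset_scan` (0-based), `run` and `trial` columns for
#' convenience.
#'
#' @param schedule an `event_schedule`.
#' @param path output file.
#' @param duration stimulus duration written to every row (seconds).
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path, duration = 1.5) {
  stopifnot(inherits(schedule, "event_schedule"))
  df <- data.frame(onset = schedule$onset_seconds,
                   duration = duration,
                   trial_type = schedule$condition,
                   onset_scan = schedule$onset_scan,
                   run = schedule$run,
                   trial = schedule$trial)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event schedule from tab-separated text
#'
#' Expects at least the columns `onset`, `duration`, `trial_type`. Onsets are
#' validated against the scan grid: `onset / tr_seconds` must be integral to
#' within 1e-6 s unless `snap = TRUE`, in which case off-grid onsets are
#' rounded to the nearest scan. Missing `run`/`trial` columns default to one
#' run with one trial per event.
#'
#' @param path input file.
#' @param tr_seconds repetition time defining the scan grid.
#' @param snap snap off-grid onsets to the nearest scan instead of erroring.
#' @return An `event_schedule` (empty, with a warning, for a header-only
#'   file).
#' @export
read_events <- function(path, tr_seconds, snap = FALSE) {
  if (!file.exists(path)) stop("no such events file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("onset", "duration", "trial_type")
  if (!all(needed %in% names(df))) {
    stop(sprintf("events file %s must have columns: %s", path,
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("events file has a header but no rows; empty schedule")
    empty <- data.frame(run = integer(0), trial = integer(0),
                        onset_scan = integer(0), onset_seconds = numeric(0),
                        condition = character(0))
    return(new_event_schedule(empty, tr_seconds))
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$onset))))
  if (length(bad)) {
    stop(sprintf("malformed onset value(s) at line(s): %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  df$onset <- as.numeric(df$onset)
  scans <- df$onset / tr_seconds
  off <- abs(scans - round(scans)) * tr_seconds > 1e-6
  if (any(off) && !snap) {
    stop(sprintf("onset(s) at line(s) %s are off the %g-s scan grid (use snap = TRUE to round)",
                 paste(which(off) + 1L, collapse = ", "), tr_seconds),
         call. = FALSE)
  }
  out <- data.frame(
    run = if ("run" %in% names(df)) as.integer(df$run) else 1L,
    trial = if ("trial" %in% names(df)) as.integer(df$trial) else seq_len(nrow(df)),
    onset_scan = as.integer(round(scans)),
    condition = df$trial_type,
    stringsAsFactors = FALSE)
  out$onset_seconds <- out$onset_scan * tr_seconds
  new_event_schedule(out, tr_seconds)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write a BOLD dataset as a delimited matrix plus sidecar header
#'
#' The matrix file is tab-separated, voxels in rows (first column
#' `voxel_id`), runs concatenated along columns. The sidecar
#' `<path>.meta.yaml` records TR, run lengths, group label and the discard
#' count; the schedule, if any, is written alongside as `<path>.events.tsv`.
#'
#' @param dataset a `bold_dataset`.
#' @param path output matrix file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(dataset, path) {
  stopifnot(inherits(dataset, "bold_dataset"))
  Y <- do.call(cbind, dataset$runs)
  df <- data.frame(voxel_id = dataset$voxel_ids,
                   format(Y, digits = 15, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("voxel_id", sprintf("t%04d", seq_len(ncol(Y))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(tr_seconds = dataset$tr_seconds,
                        n_runs = length(dataset$runs),
                        scans_per_run = n_scans_per_run(dataset),
                        group_label = dataset$group_label,
                        discarded = dataset$discarded),
                   sidecar_path(path))
  if (!is.null(dataset$schedule) && nrow(dataset$schedule) > 0L) {
    write_events(dataset$schedule, paste0(path, ".events.tsv"))
  }
  invisible(path)
}

#' Read a BOLD dataset written by [write_timeseries()]
#'
#' @param path matrix file; the sidecar `<path>.meta.yaml` must exist, and
#'   `<path>.events.tsv` is read as the schedule when present.
#' @return A `bold_dataset`.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such time-series file: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("missing sidecar header: expected %s", sc), call. = FALSE)
  }
  meta <- yaml::read_yaml(sc)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  Y <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(Y) <- "double"
  total <- meta$n_runs * meta$scans_per_run
  if (ncol(Y) != total) {
    stop(sprintf("matrix has %d time points but sidecar declares %d runs x %d scans",
                 ncol(Y), meta$n_runs, meta$scans_per_run), call. = FALSE)
  }
  runs <- lapply(seq_len(meta$n_runs), function(r) {
    Y[, (r - 1L) * meta$scans_per_run + seq_len(meta$scans_per_run),
      drop = FALSE]
  })
  evp <- paste0(path, ".events.tsv")
  sched <- if (file.exists(evp)) read_events(evp, meta$tr_seconds) else NULL
  new_bold_dataset(runs, meta$tr_seconds, df$voxel_id, meta$group_label,
                   sched, discarded = meta$discarded %||% 0L)
}

#' Export a BOLD dataset as a 4-D NIfTI volume
#'
#' Writes the voxel-by-time matrix as an `nvox x 1 x 1 x T` NIfTI image
#' (runs concatenated in time) for interoperability with imaging tools.
#' Requires the RNifti package.
#'
#' @param dataset a `bold_dataset`.
#' @param path output `.nii` / `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_timeseries_nifti <- function(dataset, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export", call. = FALSE)
  }
  Y <- do.call(cbind, dataset$runs)
  arr <- array(t(Y), dim = c(ncol(Y), 1L, 1L, nrow(Y)))
  arr <- aperm(arr, c(4, 2, 3, 1)) # nvox x 1 x 1 x T
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, dataset$tr_seconds))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D NIfTI volume into a voxel-by-time matrix
#'
#' @param path NIfTI file.
#' @param mask optional logical array over the first three dimensions (or
#'   vector of linear voxel indices); defaults to all voxels.
#' @return A numeric matrix, voxels in rows.
#' @export
read_timeseries_nifti <- function(path, mask = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI import", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D NIfTI volume", call. = FALSE)
  M <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  if (!is.null(mask)) {
    idx <- if (is.logical(mask)) which(as.vector(mask)) else as.integer(mask)
    if (any(idx < 1L | idx > nrow(M))) {
      stop("mask does not match the volume dimensions", call. = FALSE)
    }
    M <- M[idx, , drop = FALSE]
  }
  M
}
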