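#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the experiment configuration,
#' the wavelet/denoising settings, voxel-selection and estimation options,
#' group sizes and the seed. Serialises losslessly to YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param experiment an [experiment_config()].
#' @param wavelet a [wavelet_spec()].
#' @param criterion MDL criterion used by the denoising stage.
#' @param n_select top-voxel count.
#' @param methods HRF estimation methods to run.
#' @param n_subjects named vector of subjects per group (two groups are
#'   compared; defaults small so a demonstration run stays quick).
#' @param skip_denoise drop the denoising stage (analysis on raw series).
#' @param seed master seed.
#' @param log_level `"quiet"` or `"stage"` (one message per stage).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = experiment_config(),
                            wavelet = wavelet_spec(),
                            criterion = c("rmdl", "cmdl"),
                            n_select = 32L,
                            methods = c("averaging", "deconvolution"),
                            n_subjects = c(young = 3L, nondemented = 3L),
                            skip_denoise = FALSE,
                            seed = 1L,
                            log_level = c("stage", "quiet")) {
  criterion <- match.arg(criterion)
  log_level <- match.arg(log_level)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(inherits(experiment, "experiment_config"),
            inherits(wavelet, "wavelet_spec"))
  structure(list(experiment = experiment, wavelet = wavelet,
                 criterion = criterion, n_select = as.integer(n_select),
                 methods = methods, n_subjects = n_subjects,
                 skip_denoise = isTRUE(skip_denoise),
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$experiment <- unclass(x$experiment)
  x$experiment$group_snr <- as.list(x$experiment$group_snr)
  x$wavelet <- unclass(x$wavelet)
  x$n_subjects <- as.list(x$n_subjects)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  ec <- x$experiment
  experiment <- experiment_config(
    tr_seconds = ec$tr_seconds, volumes_per_run = ec$volumes_per_run,
    n_runs = ec$n_runs, trials_per_run = ec$trials_per_run,
    discard_initial = ec$discard_initial,
    pair_interval_seconds = ec$pair_interval_seconds,
    trial_window_scans = ec$trial_window_scans,
    hrf_length_scans = ec$hrf_length_scans,
    group_snr = unlist(ec$group_snr),
    n_active_voxels = ec$n_active_voxels,
    n_inactive_voxels = ec$n_inactive_voxels,
    noise_model = ec$noise_model, ar_coef = ec$ar_coef,
    drift_amplitude = ec$drift_amplitude,
    drift_period_seconds = ec$drift_period_seconds,
    baseline = ec$baseline,
    stim_duration_seconds = ec$stim_duration_seconds)
  wavelet <- wavelet_spec(family = x$wavelet$family,
                          levels = x$wavelet$levels,
                          boundary = x$wavelet$boundary)
  pipeline_config(experiment = experiment, wavelet = wavelet,
                  criterion = x$criterion, n_select = x$n_select,
                  methods = x$methods,
                  n_subjects = unlist(x$n_subjects),
                  skip_denoise = x$skip_denoise, seed = x$seed,
                  log_level = x$log_level)
}

# Result-table writer; a leading comment line stamps the config hash so
# every table carries its provenance (read back with comment.char = "#").
write_tsv <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the simulate - denoise - detect - estimate - compare pipeline
#'
#' Executes the full analysis chain on synthetic data and writes per-stage
#' artifacts under `out_dir`: event and time-series files for one exemplar
#' subject, per-subject t-statistic and selected-voxel tables, HRF curves
#' with SEM, per-subject peaks, the group comparison, and a `manifest.json`
#' recording the package version, seed, config hash and per-stage counts.
#' Identical config and seed give byte-identical result tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly (a list; its `stages` entry has one
#'   element per completed stage).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$log_level == "stage") message(sprintf(...))
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  groups <- names(config$n_subjects)[1:2]
  denoise <- if (config$skip_denoise) "none" else config$criterion
  manifest <- list(package = "mdlhrf",
                   version = as.character(utils::packageVersion("mdlhrf")),
                   seed = config$seed, config_hash = config_hash,
                   stages = list())
  stage <- function(name, counts) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      c(list(name = name), counts)
  }

  on_fail <- function(name, e) {
    stage(name, list(failed = TRUE, error = conditionMessage(e)))
    manifest$completed <<- FALSE
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  }

  total <- sum(config$n_subjects[groups])
  seeds <- derive_seeds(config$seed, total)

  # -- simulate -------------------------------------------------------------
  sims <- tryCatch({
    sidx <- 0L
    out <- list()
    for (g in groups) {
      for (s in seq_len(config$n_subjects[[g]])) {
        sidx <- sidx + 1L
        out[[sprintf("%s_%02d", g, s)]] <-
          simulate_subject(config$experiment, group = g, seed = seeds[sidx])
      }
    }
    write_events(out[[1]]$dataset$schedule,
                 file.path(out_dir, "subject01_events.tsv"))
    write_timeseries(out[[1]]$dataset,
                     file.path(out_dir, "subject01_bold.tsv"))
    out
  }, error = function(e) on_fail("simulate", e))
  stage("simulate", list(n_subjects = total,
                         n_trials = length(unique(sims[[1]]$dataset$schedule$trial))))
  say("simulate: %d subjects (%s)", total,
      paste(sprintf("%s=%d", groups, config$n_subjects[groups]), collapse = ", "))

  # -- denoise --------------------------------------------------------------
  if (denoise != "none") {
    analysed_data <- tryCatch({
      lapply(sims, function(sim) denoise_dataset(sim$dataset, config$wavelet,
                                                 criterion = denoise))
    }, error = function(e) on_fail("denoise", e))
    ktab <- do.call(rbind, lapply(names(analysed_data), function(nm) {
      k <- attr(analysed_data[[nm]], "mdl_k")
      cbind(subject = nm, k)
    }))
    write_tsv(ktab, file.path(out_dir, "mdl_k.tsv"), config_hash)
    stage("denoise", list(criterion = denoise, median_k = stats::median(ktab$k)))
    say("denoise: %s, median k = %s", denoise, stats::median(ktab$k))
  } else {
    analysed_data <- lapply(sims, function(sim) sim$dataset)
    say("denoise: skipped")
  }

  # -- detect ---------------------------------------------------------------
  detect <- tryCatch({
    lapply(names(analysed_data), function(nm) {
      tm <- tstat_map(analysed_data[[nm]])
      vs <- select_top_voxels(tm, config$n_select)
      tm$selected <- tm$voxel_id %in% vs$voxel_id
      tm$subject <- nm
      list(tmap = tm, voxels = vs)
    })
  }, error = function(e) on_fail("detect", e))
  names(detect) <- names(analysed_data)
  write_tsv(do.call(rbind, lapply(detect, `[[`, "tmap")),
            file.path(out_dir, "tstats.tsv"), config_hash)
  stage("detect", list(n_select = config$n_select))
  say("detect: top-%d voxels per subject", config$n_select)

  # -- estimate -------------------------------------------------------------
  est <- tryCatch({
    rows <- list()
    peaks <- list()
    for (nm in names(analysed_data)) {
      g <- sub("_[0-9]+$", "", nm)
      for (m in config$methods) {
        roi <- mean_roi_hrf(analysed_data[[nm]], detect[[nm]]$voxels,
                            method = m, L = config$experiment$hrf_length_scans)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = nm, group = g, method = m,
          lag_seconds = roi$curve$lag_seconds,
          percent_change = roi$curve$samples, sem = roi$sem,
          stringsAsFactors = FALSE)
        peaks[[length(peaks) + 1L]] <- data.frame(
          subject = nm, group = g, method = m,
          peak = hrf_peak(roi$curve)$amplitude,
          latency_seconds = hrf_peak(roi$curve)$latency_seconds,
          stringsAsFactors = FALSE)
      }
    }
    list(curves = do.call(rbind, rows), peaks = do.call(rbind, peaks))
  }, error = function(e) on_fail("estimate", e))
  write_tsv(est$curves, file.path(out_dir, "hrf_curves.tsv"), config_hash)
  write_tsv(est$peaks, file.path(out_dir, "hrf_peaks.tsv"), config_hash)
  stage("estimate", list(methods = config$methods))
  say("estimate: %s", paste(config$methods, collapse = " + "))

  # -- compare --------------------------------------------------------------
  cmp_tab <- tryCatch({
    do.call(rbind, lapply(config$methods, function(m) {
      pk <- est$peaks[est$peaks$method == m, ]
      cmp <- compare_groups(pk$peak[pk$group == groups[1]],
                            pk$peak[pk$group == groups[2]],
                            labels = groups)
      data.frame(method = m, group_a = groups[1], group_b = groups[2],
                 t = cmp$t_statistic, df = cmp$df, p = cmp$p_value,
                 significant = cmp$significant, stringsAsFactors = FALSE)
    }))
  }, error = function(e) on_fail("compare", e))
  write_tsv(cmp_tab, file.path(out_dir, "group_comparison.tsv"), config_hash)
  stage("compare", list(groups = groups))
  say("compare: %s vs %s", groups[1], groups[2])

  manifest$completed <- TRUE
  manifest$config_hash <- config_hash
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
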