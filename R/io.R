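#' Write a multichannel EEG recording as plain CSV
#'
#' Column 1 is `time_s` (seconds from recording start, 6-decimal fixed
#' format), remaining columns `ch1..chN` in microvolts. The sampling rate is
#' recovered from the time axis on read.
#'
#' @param eeg An `eeg_sim` or samples x channels matrix.
#' @param path Output path.
#' @param fs_hz Sampling rate (needed for a bare matrix).
#' @return The path, invisibly.
#' @export
write_eeg_csv <- function(eeg, path, fs_hz = NULL) {
  if (inherits(eeg, "eeg_sim")) {
    sig <- eeg$signal; fs_hz <- eeg$fs_hz
  } else {
    sig <- as.matrix(eeg)
    if (is.null(fs_hz)) stop("fs_hz required")
  }
  df <- data.frame(time_s = sprintf("%.6f", (seq_len(nrow(sig)) - 1) / fs_hz))
  for (ch in seq_len(ncol(sig))) df[[sprintf("ch%d", ch)]] <- sig[, ch]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-CSV EEG recording
#'
#' @param path CSV written by [write_eeg_csv()] (or any table with a
#'   `time_s` column and one column per channel).
#' @return An `eeg_sim` (signal matrix + `fs_hz`).
#' @export
read_eeg_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df)) stop("EEG CSV needs a time_s column")
  dt <- diff(df$time_s)
  if (length(dt) < 1L || any(dt <= 0)) stop("time axis must increase")
  fs <- 1 / stats::median(dt)
  sig <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  structure(list(signal = unname(sig), fs_hz = round(fs, 6),
                 duration_s = nrow(sig) / fs),
            class = "eeg_sim")
}

#' Export a burst table with a JSON schema sidecar
#'
#' @param fit An `eeg_bursts` object (or a burst table data frame).
#' @param path Output CSV path; the sidecar is `<path>.schema.json`.
#' @return The path, invisibly.
#' @export
export_bursts <- function(fit, path) {
  tab <- if (inherits(fit, "eeg_bursts")) fit$table else fit
  tab$start_s <- sprintf("%.6f", tab$start_s)
  tab$end_s <- sprintf("%.6f", tab$end_s)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  schema <- list(
    columns = list(
      channel = "1-based channel index",
      band = "filter band label (Hz)",
      polarity = "direct | inverted",
      start_s = "burst start, seconds from recording start",
      end_s = "burst end (half-open), seconds",
      n_cycles = "number of criterion-passing cycles",
      mean_freq_hz = "reciprocal mean inter-negative-peak interval",
      mean_amp_uV = "mean cycle amplitude (rise/decay average)"))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Default run configuration
#'
#' All analysis constants in one serialisable list: band set, per-cycle
#' criteria thresholds, Welch parameters, edge-channel exclusions, pupil
#' thresholds and the session schedule. The defaults reproduce the method's
#' published constants.
#'
#' @return Named list of class `run_config`.
#' @export
run_config <- function() {
  structure(list(
    bands = lapply(default_bands(), function(b) c(low = b$low,
                                                  high = b$high)),
    criteria = unclass(criteria_thresholds()),
    filter = unclass(filter_spec()),
    welch = list(window_s = 8, overlap = 0.75),
    edge_channels = edge_channels(),
    pupil = list(confidence_threshold = 0.5, hysteresis_s = 0.05,
                 blink_cutoff_s = 1, gap_s = 0.5,
                 epoch_s = c(-0.5, 2), baseline_s = c(-0.5, 0),
                 auc_s = c(0.5, 2), min_clean_frac = 2 / 3,
                 min_trials = 15, min_per_timepoint = 10,
                 min_sessions = 6),
    schedule = as.list(session_schedule()),
    alpha = 0.05, fdr_q = 0.05,
    seed = 1L),
    class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys are an error, so a typo never silently falls back to a
#' default.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config: %s", path))
  raw <- yaml::read_yaml(path)
  base <- run_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  base[names(raw)] <- raw
  class(base) <- "run_config"
  base
}

#' @rdname read_run_config
#' @param config A `run_config` to serialise.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the config hash, seed, package version and R version next to the
#' results so any table can be traced back to the run that produced it.
#'
#' @param config_path Path of the config file used (hashed), or `NA`.
#' @param seed Seed used for the run.
#' @param out_dir Directory the manifest is written into.
#' @return Manifest list, invisibly.
#' @export
write_manifest <- function(config_path, seed, out_dir) {
  manifest <- list(
    config = if (!is.na(config_path) && file.exists(config_path))
      list(path = config_path,
           md5 = unname(tools::md5sum(config_path))) else NULL,
    seed = seed,
    package = as.character(utils::packageVersion("cyclebursts")),
    r_version = R.version.string,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
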