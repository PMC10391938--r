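#' Detect oscillation bursts in a multichannel EEG recording
#'
#' Runs the complete cycle-by-cycle pipeline on every channel: narrowband
#' filtering in each band of the bank, zero-crossing and peak parsing,
#' per-cycle criteria, run formation on both polarities, within-channel
#' overlap resolution, and cross-channel aggregation into reference bursts.
#'
#' @param eeg Numeric matrix, channels in columns, samples in rows
#'   (microvolts), or a vector for a single channel.
#' @param fs_hz Sampling rate in Hz (>= 100; the method targets 250 Hz
#'   recordings band-passed 0.5-40 Hz).
#' @param bands List of [band_definition()]s; default [default_bands()].
#' @param thresholds A [criteria_thresholds()].
#' @param spec A [filter_spec()].
#' @param freq_overlap_only Logical; when aggregating, compare mean
#'   frequencies computed over the temporally overlapping cycles only
#'   (default) rather than whole-burst frequencies.
#' @param preprocess_bp Broadband band-pass `c(low, high)` in Hz applied
#'   before detection to obtain the minimally filtered signal on which peaks
#'   are located (default `c(0.5, 40)`); `NULL` skips it (input already
#'   preprocessed).
#' @return Object of class `eeg_bursts`: list with `bursts` (per-channel
#'   resolved burst records), `aggregates` (see
#'   [aggregate_across_channels()]), `table` (one row per burst),
#'   `fs_hz`, `n_samples`, `n_channels`, `duration_s`.
#' @examples
#' sim <- gen_aperiodic_eeg(30, 250, exponent = 1, scale_uV = 10,
#'                          n_channels = 1, seed = 1)
#' withb <- insert_bursts(sim, data.frame(channel = 1, freq_hz = 6,
#'                                        n_cycles = 10, amp_uV = 60,
#'                                        onset_s = 10))
#' fit <- detect_eeg_bursts(withb$signal, fs_hz = 250)
#' summary(fit)
#' @export
detect_eeg_bursts <- function(eeg, fs_hz, bands = default_bands(),
                              thresholds = criteria_thresholds(),
                              spec = filter_spec(),
                              freq_overlap_only = TRUE,
                              preprocess_bp = c(0.5, 40)) {
  if (is.vector(eeg)) eeg <- matrix(eeg, ncol = 1)
  stopifnot(is.matrix(eeg), fs_hz >= 100)
  n_ch <- ncol(eeg)
  filters <- lapply(bands, design_band_filter, fs_hz = fs_hz, spec = spec)
  per_channel <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    raw <- eeg[, ch]
    if (!is.null(preprocess_bp))
      raw <- bandpass_broadband(raw, fs_hz, preprocess_bp[1],
                                preprocess_bp[2])
    cand <- list()
    for (flt in filters) {
      cand <- c(cand, detect_dual_polarity(raw, flt, thresholds, ch))
    }
    per_channel[[ch]] <- resolve_within_channel(cand, thresholds$min_cycles)
  }
  all_bursts <- do.call(c, per_channel)
  agg <- aggregate_across_channels(all_bursts,
                                   freq_overlap_only = freq_overlap_only)
  structure(list(bursts = all_bursts, aggregates = agg,
                 table = burst_table(all_bursts),
                 fs_hz = fs_hz, n_samples = nrow(eeg), n_channels = n_ch,
                 duration_s = nrow(eeg) / fs_hz,
                 thresholds = thresholds, bands = bands),
            class = "eeg_bursts")
}

#' Tabulate burst records
#'
#' @param bursts List of burst records.
#' @return Data frame with one row per burst: channel, band, polarity,
#'   start_s, end_s, n_cycles, mean_freq_hz, mean_amp_uV.
#' @export
burst_table <- function(bursts) {
  if (length(bursts) == 0L)
    return(data.frame(channel = integer(), band = character(),
                      polarity = character(), start_s = numeric(),
                      end_s = numeric(), n_cycles = integer(),
                      mean_freq_hz = numeric(), mean_amp_uV = numeric()))
  data.frame(
    channel = vapply(bursts, `[[`, 0L, "channel"),
    band = vapply(bursts, `[[`, "", "band"),
    polarity = vapply(bursts, `[[`, "", "polarity"),
    start_s = vapply(bursts, `[[`, 0, "start_s"),
    end_s = vapply(bursts, `[[`, 0, "end_s"),
    n_cycles = vapply(bursts, function(b) as.integer(b$n_cycles), 0L),
    mean_freq_hz = vapply(bursts, `[[`, 0, "mean_freq"),
    mean_amp_uV = vapply(bursts, `[[`, 0, "mean_amp"))
}

#' @export
print.eeg_bursts <- function(x, ...) {
  cat(sprintf(
    "eeg_bursts: %d bursts (%d aggregated) in %d channel(s), %.1f s at %g Hz\n",
    nrow(x$table), length(x$aggregates), x$n_channels, x$duration_s,
    x$fs_hz))
  invisible(x)
}

#' @export
summary.eeg_bursts <- function(object, ...) {
  met <- recording_metrics(object$aggregates, object$duration_s)
  cat(sprintf("Cycle-by-cycle burst detection: %.1f s, %d channel(s), %g Hz\n",
              object$duration_s, object$n_channels, object$fs_hz))
  cat(sprintf("  %d within-channel bursts -> %d aggregated bursts\n",
              nrow(object$table), length(object$aggregates)))
  print(met, row.names = FALSE)
  invisible(met)
}

#' @export
plot.eeg_bursts <- function(x, channel = 1L, eeg = NULL, ...) {
  tab <- x$table[x$table$channel == channel, , drop = FALSE]
  if (!is.null(eeg)) {
    t <- (seq_len(x$n_samples) - 1) / x$fs_hz
    graphics::plot(t, eeg[, channel], type = "l", col = "grey50",
                   xlab = "time (s)", ylab = "amplitude (uV)", ...)
    for (i in seq_len(nrow(tab)))
      graphics::rect(tab$start_s[i], min(eeg[, channel]), tab$end_s[i],
                     max(eeg[, channel]), col = grDevices::adjustcolor(
                       "tomato", 0.2), border = NA)
  } else {
    graphics::plot(NA, xlim = c(0, x$duration_s),
                   ylim = c(0.5, max(1, nrow(tab)) + 0.5),
                   xlab = "time (s)", ylab = "burst", ...)
    if (nrow(tab))
      graphics::segments(tab$start_s, seq_len(nrow(tab)), tab$end_s,
                         seq_len(nrow(tab)), lwd = 3)
  }
  invisible(x)
}
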