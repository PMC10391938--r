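#' Band-limited background noise level
#'
#' Standard deviation of a background signal after narrowband filtering,
#' used to set burst amplitudes at a requested signal-to-noise ratio:
#' SNR = peak-to-peak amplitude / (2 x background SD in the burst's band).
#'
#' @param x Background signal vector.
#' @param band A [band_definition()].
#' @param fs_hz Sampling rate.
#' @return Standard deviation (microvolts).
#' @export
band_noise_sd <- function(x, band, fs_hz) {
  stats::sd(apply_band_filter(x, design_band_filter(band, fs_hz)))
}

#' Detector validation fixture: known bursts over 1/f background
#'
#' Emulates an oscillation-rich resting recording: theta (6 Hz, 10 cycles)
#' and alpha (10 Hz, 12 cycles) bursts alternate on a 1/f background, every
#' burst present on all channels (real bursts extend across electrodes),
#' with amplitudes set per band to a fixed SNR. Bursts are kept clear of the
#' filter-edge exclusion zones.
#'
#' @param seed Integer seed.
#' @param snr Peak-to-peak amplitude over twice the band-limited background
#'   SD (default 5).
#' @param n_bursts Number of burst events (default 20, alternating bands).
#' @param n_channels Channels (default 3).
#' @param fs_hz Sampling rate (default 250).
#' @param exponent Background 1/f exponent (default 1).
#' @param scale_uV Background SD (default 10).
#' @param gap_s Quiet time between consecutive bursts (default 1).
#' @param lead_s Quiet lead-in/lead-out (default 5.2, beyond the slowest
#'   band's filter-edge region).
#' @return List with `signal` (an `eeg_sim`), `truth` (per-channel
#'   ground-truth rows from [insert_bursts()]) and `events` (one row per
#'   burst event: `onset_s`, `dur_s`, `freq_hz`, `n_cycles`, `amp_uV`).
#' @export
burst_validation_fixture <- function(seed, snr = 5, n_bursts = 20L,
                                     n_channels = 3L, fs_hz = 250,
                                     exponent = 1, scale_uV = 10,
                                     gap_s = 1, lead_s = 5.2) {
  freq <- rep(c(6, 10), length.out = n_bursts)
  ncyc <- rep(c(10L, 12L), length.out = n_bursts)
  wave <- (ncyc + 2) / freq
  onset <- cumsum(c(lead_s, utils::head(wave, -1) + gap_s))
  dur <- max(onset + wave) + lead_s
  bg <- gen_aperiodic_eeg(dur, fs_hz, exponent = exponent,
                          scale_uV = scale_uV, n_channels = n_channels,
                          seed = seed)
  sd_theta <- band_noise_sd(bg$signal[, 1], band_definition(4, 8), fs_hz)
  sd_alpha <- band_noise_sd(bg$signal[, 1], band_definition(8, 12), fs_hz)
  amp <- snr * 2 * ifelse(freq < 8, sd_theta, sd_alpha)
  specs <- do.call(rbind, lapply(seq_len(n_channels), function(ch)
    data.frame(channel = ch, freq_hz = freq, n_cycles = ncyc,
               amp_uV = amp, onset_s = onset)))
  sim <- insert_bursts(bg, specs)
  list(signal = sim$signal, truth = sim$truth,
       events = data.frame(onset_s = onset + 1.25 / freq,
                           dur_s = ncyc / freq, freq_hz = freq,
                           n_cycles = ncyc, amp_uV = amp))
}

#' Match detected burst intervals against ground truth
#'
#' A truth event counts as recovered when some detected interval covers at
#' least `min_overlap` of the event's duration (sensitivity); a detection
#' counts as correct when some truth event covers at least `min_overlap` of
#' the detection's duration (precision).
#'
#' @param events Ground-truth events (`onset_s`, `dur_s`).
#' @param intervals Detections: data frame with `start_s`, `end_s` (e.g.
#'   aggregate spans or a burst table).
#' @param min_overlap Fractional overlap required (default 0.5).
#' @return List with `sensitivity`, `precision`, `n_truth`, `n_detected`.
#' @export
match_bursts <- function(events, intervals, min_overlap = 0.5) {
  t0 <- events$onset_s; t1 <- events$onset_s + events$dur_s
  d0 <- intervals$start_s; d1 <- intervals$end_s
  ivo <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
  sens <- if (length(t0) == 0L) NA_real_ else
    mean(vapply(seq_along(t0), function(i)
      any(ivo(t0[i], t1[i], d0, d1) >= min_overlap * (t1[i] - t0[i])),
      TRUE))
  prec <- if (length(d0) == 0L) NA_real_ else
    mean(vapply(seq_along(d0), function(j)
      any(ivo(t0, t1, d0[j], d1[j]) >= min_overlap * (d1[j] - d0[j])),
      TRUE))
  list(sensitivity = sens, precision = prec,
       n_truth = length(t0), n_detected = length(d0))
}

#' Spans of multichannel aggregated bursts
#'
#' Convenience extractor: reference-burst spans of aggregates, optionally
#' restricted to aggregates supported by a minimum number of distinct
#' channels (single-channel events in noise rarely replicate across
#' channels, so the multichannel consensus is the detection unit for
#' validation).
#'
#' @param fit An `eeg_bursts` object.
#' @param min_channels Minimum distinct member channels (default 1).
#' @return Data frame `start_s`, `end_s`, `band`, `n_channels`, `n_cycles`.
#' @export
aggregate_spans <- function(fit, min_channels = 1L) {
  agg <- fit$aggregates
  nch <- vapply(agg, function(a)
    length(unique(vapply(a$members, `[[`, 0L, "channel"))), 0L)
  agg <- agg[nch >= min_channels]
  data.frame(
    start_s = vapply(agg, `[[`, 0, "start_s"),
    end_s = vapply(agg, `[[`, 0, "end_s"),
    band = vapply(agg, `[[`, "", "band"),
    n_channels = nch[nch >= min_channels],
    n_cycles = vapply(agg, function(a) as.integer(a$n_cycles), 0L))
}
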