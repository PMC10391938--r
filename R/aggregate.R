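#' Mean frequency of a burst
#'
#' Defined as the reciprocal of the mean interval between consecutive
#' negative peaks of the burst's cycles.
#'
#' @param burst A burst record.
#' @param window Optional numeric `c(start, end)` sample window; only
#'   negative peaks inside it are used (for overlap-restricted frequency).
#' @return Frequency in Hz, or `NA` when fewer than two negative peaks are
#'   available.
#' @export
burst_frequency <- function(burst, window = NULL) {
  negs <- sort(burst$cycles$neg)
  if (!is.null(window)) negs <- negs[negs >= window[1] & negs < window[2]]
  if (length(negs) < 2L) return(NA_real_)
  1 / mean(diff(negs) / burst$fs_hz)
}

#' Assign a burst frequency to a canonical band
#'
#' Theta is 4-8 Hz and alpha 8-12 Hz; boundaries are half-open at the upper
#' edge, so exactly 8 Hz is alpha. Frequencies outside both bands are
#' `"other"`.
#'
#' @param freq_hz Numeric frequency (vectorised).
#' @return Character vector: `"theta"`, `"alpha"` or `"other"`.
#' @export
band_assign <- function(freq_hz) {
  out <- rep("other", length(freq_hz))
  out[!is.na(freq_hz) & freq_hz >= 4 & freq_hz < 8] <- "theta"
  out[!is.na(freq_hz) & freq_hz >= 8 & freq_hz < 12] <- "alpha"
  out[is.na(freq_hz)] <- NA_character_
  out
}

#' Aggregate bursts across channels
#'
#' Bursts that co-occur on different channels are treated as one event. The
#' grouping is greedy: the longest unassigned burst seeds an aggregate and
#' becomes its reference; an unassigned candidate from another channel joins
#' if its temporal overlap with the reference covers at least half of the
#' candidate's own duration and the mean frequencies over the overlapping
#' cycles differ by at most 1 Hz. Every burst belongs to at most one
#' aggregate.
#'
#' @param bursts List of overlap-resolved burst records (any channels).
#' @param min_overlap Fraction of the candidate's duration that must overlap
#'   the reference (default 0.5).
#' @param max_freq_diff Maximum absolute frequency difference in Hz
#'   (default 1).
#' @param freq_overlap_only Compare frequencies computed over the overlapping
#'   cycles only (default `TRUE`); otherwise whole-burst frequencies.
#' @return List of aggregates: each a list with `reference`, `members`
#'   (including the reference), `mean_freq` (Hz, over all member cycles),
#'   `mean_amp` (microvolts, mean over all member cycles of the per-cycle
#'   rise/decay average), `band` (theta/alpha/other), `start_s`, `end_s`,
#'   `n_cycles` (reference cycle count).
#' @export
aggregate_across_channels <- function(bursts, min_overlap = 0.5,
                                      max_freq_diff = 1,
                                      freq_overlap_only = TRUE) {
  if (length(bursts) == 0L) return(list())
  n <- length(bursts)
  dur <- vapply(bursts, function(b) b$end - b$start, 0)
  ord <- order(-vapply(bursts, `[[`, 0L, "n_cycles"), -dur,
               vapply(bursts, `[[`, 0, "start"))
  assigned <- logical(n)
  aggregates <- list()
  for (i in ord) {
    if (assigned[i]) next
    ref <- bursts[[i]]
    assigned[i] <- TRUE
    members <- list(ref)
    for (j in ord) {
      if (assigned[j]) next
      cand <- bursts[[j]]
      if (cand$channel == ref$channel) next
      ov <- min(ref$end, cand$end) - max(ref$start, cand$start)
      if (ov <= 0) next
      if (ov / (cand$end - cand$start) < min_overlap) next
      win <- c(max(ref$start, cand$start), min(ref$end, cand$end))
      if (freq_overlap_only) {
        f_ref <- burst_frequency(ref, win)
        f_cand <- burst_frequency(cand, win)
        if (is.na(f_ref)) f_ref <- ref$mean_freq
        if (is.na(f_cand)) f_cand <- cand$mean_freq
      } else {
        f_ref <- ref$mean_freq
        f_cand <- cand$mean_freq
      }
      if (is.na(f_ref) || is.na(f_cand) ||
          abs(f_ref - f_cand) > max_freq_diff) next
      assigned[j] <- TRUE
      members[[length(members) + 1L]] <- cand
    }
    all_cycles <- do.call(rbind, lapply(members, function(b)
      b$cycles[, c("neg", "amp"), drop = FALSE]))
    aggregates[[length(aggregates) + 1L]] <- list(
      reference = ref, members = members,
      mean_freq = ref$mean_freq,
      mean_amp = mean(all_cycles$amp),
      band = band_assign(ref$mean_freq),
      start_s = ref$start_s, end_s = ref$end_s,
      n_cycles = ref$n_cycles)
  }
  aggregates[order(vapply(aggregates, `[[`, 0, "start_s"))]
}

#' Recording-level burst metrics per band
#'
#' Amplitude follows a three-level average: rise and decay amplitudes are
#' averaged within each cycle, these cycle amplitudes are averaged across all
#' cycles of all member bursts of an aggregate, and the aggregate amplitudes
#' are averaged within each band (burst-level, not cycle-weighted). Quantity
#' is the summed reference-burst cycle count per minute of recording;
#' occupancy is the fraction of the recording covered by reference bursts.
#'
#' @param aggregates List from [aggregate_across_channels()].
#' @param duration_s Recording duration in seconds (> 0).
#' @param bands Character vector of band labels to report.
#' @return Data frame with one row per band: `band`, `n_bursts`,
#'   `mean_amp_uV`, `cycles_per_min`, `occupancy`. Metrics for a band with no
#'   bursts are reported as `NA` (missing, not zero), with `n_bursts = 0`.
#' @export
recording_metrics <- function(aggregates, duration_s,
                              bands = c("theta", "alpha")) {
  stopifnot(duration_s > 0)
  lab <- vapply(aggregates, `[[`, "", "band")
  out <- lapply(bands, function(bd) {
    sel <- aggregates[!is.na(lab) & lab == bd]
    if (length(sel) == 0L)
      return(data.frame(band = bd, n_bursts = 0L, mean_amp_uV = NA_real_,
                        cycles_per_min = NA_real_, occupancy = NA_real_))
    amp <- mean(vapply(sel, `[[`, 0, "mean_amp"))
    cyc <- sum(vapply(sel, `[[`, 0L, "n_cycles"))
    cover <- sum(vapply(sel, function(a) a$end_s - a$start_s, 0))
    data.frame(band = bd, n_bursts = length(sel), mean_amp_uV = amp,
               cycles_per_min = cyc / (duration_s / 60),
               occupancy = cover / duration_s)
  })
  do.call(rbind, out)
}
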