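#' Zero-crossings of a narrowband-filtered signal
#'
#' A descending crossing is the first sample at or past a positive-to-negative
#' sign change; a rising crossing the converse. Samples exactly at zero
#' inherit the previous sign, so the convention is deterministic and limited
#' in resolution only by the sampling rate.
#'
#' @param x Filtered numeric signal.
#' @return List with integer vectors `descending` and `rising` (1-based
#'   sample indices), strictly alternating in time.
#' @export
find_zero_crossings <- function(x) {
  stopifnot(is.numeric(x))
  if (anyNA(x) || any(!is.finite(x))) stop("signal must be finite")
  if (length(x) < 2L)
    return(list(descending = integer(), rising = integer()))
  s <- sign(x)
  # zeros inherit the previous sign (leading zeros inherit the first nonzero)
  if (any(s == 0)) {
    nz <- which(s != 0)
    if (length(nz) == 0L)
      return(list(descending = integer(), rising = integer()))
    last <- s[nz[1]]
    for (i in seq_along(s)) {
      if (s[i] == 0) s[i] <- last else last <- s[i]
    }
  }
  d <- diff(s)
  list(descending = which(d < 0) + 1L, rising = which(d > 0) + 1L)
}

#' Locate raw-signal peaks between zero-crossings
#'
#' Negative peaks are located as the minimum of the *raw* (broadband, 0.5-40
#' Hz) signal between a descending and the next rising crossing of the
#' narrowband-filtered signal; positive peaks as the maximum between a rising
#' and the next descending crossing. Spans are half-open `[from, to)`; ties
#' go to the first sample.
#'
#' @param raw Raw signal vector (same length as the filtered signal the
#'   crossings came from).
#' @param crossings Result of [find_zero_crossings()].
#' @return Data frame with columns `index` (1-based) and `kind`
#'   (`"pos"`/`"neg"`), rows ordered in time and strictly alternating.
#' @export
locate_peaks <- function(raw, crossings) {
  stopifnot(is.numeric(raw), is.list(crossings))
  ev <- data.frame(
    at = c(crossings$descending, crossings$rising),
    kind = c(rep("desc", length(crossings$descending)),
             rep("rise", length(crossings$rising))))
  if (nrow(ev) < 2L)
    return(data.frame(index = integer(), kind = character()))
  ev <- ev[order(ev$at), , drop = FALSE]
  out_idx <- integer(nrow(ev)); out_kind <- character(nrow(ev)); k <- 0L
  for (i in seq_len(nrow(ev) - 1L)) {
    from <- ev$at[i]; to <- ev$at[i + 1L]   # half-open [from, to)
    if (to <= from) next
    span <- from:(to - 1L)
    k <- k + 1L
    if (ev$kind[i] == "desc") {
      out_idx[k] <- span[which.min(raw[span])]
      out_kind[k] <- "neg"
    } else {
      out_idx[k] <- span[which.max(raw[span])]
      out_kind[k] <- "pos"
    }
  }
  data.frame(index = out_idx[seq_len(k)], kind = out_kind[seq_len(k)])
}

# per-flank monotonicity in time: fraction of sample steps moving in the
# expected direction (down on the descending flank, up on the rising flank)
.mono_time <- function(seg, direction) {
  d <- diff(seg)
  if (length(d) == 0L) return(1)
  mean(if (direction == "down") d < 0 else d > 0)
}

# per-flank monotonicity in amplitude: net correctly-signed voltage change
# over total absolute voltage change
.mono_amp <- function(seg, direction) {
  d <- diff(seg)
  tot <- sum(abs(d))
  if (tot == 0) return(1)
  net <- if (direction == "down") -sum(d) else sum(d)
  max(0, min(1, net / tot))
}

#' Parse peak sequences into cycles with per-criterion features
#'
#' One cycle spans a negative peak and its two flanking positive peaks.
#' Every interior negative peak (one with a positive peak on both sides)
#' yields a cycle; features feed the seven burst criteria. Amplitudes are in
#' the units of `raw` (microvolts), periods in seconds.
#'
#' @param peaks Peak table from [locate_peaks()].
#' @param raw Raw signal vector.
#' @param fs_hz Sampling rate in Hz.
#' @param band A [band_definition()] recorded on each cycle.
#' @return Data frame of class `cycle_frame`, one row per cycle, with columns
#'   `prev_pos`, `neg`, `next_pos` (sample indices), `rise_amp`, `decay_amp`,
#'   `amp`, `period_prev`, `period_next` (s; `NA` when the neighbouring
#'   negative peak is missing), `mono_time_rise`, `mono_time_decay`,
#'   `mono_amp`, `is_local_min`, `band`.
#' @export
build_cycles <- function(peaks, raw, fs_hz, band) {
  stopifnot(is.data.frame(peaks), is.numeric(raw), fs_hz > 0,
            inherits(band, "band_definition"))
  empty <- data.frame(
    prev_pos = integer(), neg = integer(), next_pos = integer(),
    rise_amp = numeric(), decay_amp = numeric(), amp = numeric(),
    period_prev = numeric(), period_next = numeric(),
    mono_time_rise = numeric(), mono_time_decay = numeric(),
    mono_amp = numeric(), is_local_min = logical(), band = character())
  neg <- peaks$index[peaks$kind == "neg"]
  pos <- peaks$index[peaks$kind == "pos"]
  if (length(neg) == 0L || length(pos) == 0L) {
    class(empty) <- c("cycle_frame", "data.frame")
    return(empty)
  }
  # flanking positive peaks via findInterval (peaks strictly alternate)
  ip <- findInterval(neg, pos)            # index of last pos <= neg
  keep <- ip >= 1L & ip < length(pos)
  neg_k <- neg[keep]
  if (length(neg_k) == 0L) {
    class(empty) <- c("cycle_frame", "data.frame")
    return(empty)
  }
  p0 <- pos[ip[keep]]
  p1 <- pos[ip[keep] + 1L]
  # neighbouring negative peaks for the period features
  j <- match(neg_k, neg)
  per_prev <- ifelse(j > 1L, (neg_k - neg[pmax(j - 1L, 1L)]) / fs_hz,
                     NA_real_)
  per_next <- ifelse(j < length(neg),
                     (neg[pmin(j + 1L, length(neg))] - neg_k) / fs_hz,
                     NA_real_)
  # flank statistics from cumulative sums of the sample-to-sample differences
  dd <- diff(raw)
  cs_dn <- cumsum(dd < 0)
  cs_up <- cumsum(dd > 0)
  cs_abs <- cumsum(abs(dd))
  seg <- function(cs, a, b) cs[b] - ifelse(a > 1L, cs[a - 1L], 0)
  len_rise <- neg_k - p0                  # steps on the descending flank
  len_decay <- p1 - neg_k                 # steps on the rising flank
  mono_time_rise <- ifelse(len_rise > 0,
                           seg(cs_dn, p0, neg_k - 1L) / len_rise, 1)
  mono_time_decay <- ifelse(len_decay > 0,
                            seg(cs_up, neg_k, p1 - 1L) / len_decay, 1)
  rise <- raw[p0] - raw[neg_k]
  decay <- raw[p1] - raw[neg_k]
  tot_rise <- ifelse(len_rise > 0, seg(cs_abs, p0, neg_k - 1L), 0)
  tot_decay <- ifelse(len_decay > 0, seg(cs_abs, neg_k, p1 - 1L), 0)
  clamp01 <- function(v) pmax(0, pmin(1, v))
  ma_rise <- ifelse(tot_rise > 0, clamp01(rise / tot_rise), 1)
  ma_decay <- ifelse(tot_decay > 0, clamp01(decay / tot_decay), 1)
  nr <- length(raw)
  local_min <- neg_k > 1L & neg_k < nr &
    raw[neg_k] <= raw[pmax(neg_k - 1L, 1L)] &
    raw[neg_k] <= raw[pmin(neg_k + 1L, nr)]
  cyc <- data.frame(
    prev_pos = p0, neg = neg_k, next_pos = p1,
    rise_amp = rise, decay_amp = decay, amp = (rise + decay) / 2,
    period_prev = per_prev, period_next = per_next,
    mono_time_rise = mono_time_rise, mono_time_decay = mono_time_decay,
    mono_amp = (ma_rise + ma_decay) / 2,
    is_local_min = local_min, band = band$label)
  class(cyc) <- c("cycle_frame", "data.frame")
  cyc
}

#' Full cycle parse of one channel in one band
#'
#' Convenience wrapper: filter, find zero-crossings, locate raw peaks, build
#' cycles, and mark cycles whose span touches the filter-edge region as
#' unreliable.
#'
#' @param raw Raw signal vector (broadband, microvolts).
#' @param flt A `band_filter`.
#' @return A `cycle_frame` with an extra logical column `edge_ok`.
#' @export
parse_cycles <- function(raw, flt) {
  filt <- apply_band_filter(raw, flt)
  edge <- attr(filt, "edge")
  xing <- find_zero_crossings(filt)
  pk <- locate_peaks(raw, xing)
  cyc <- build_cycles(pk, raw, flt$fs_hz, flt$band)
  cyc$edge_ok <- cyc$prev_pos >= edge[1] & cyc$next_pos <= edge[2]
  cyc
}
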