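#' Per-cycle criteria thresholds
#'
#' A cycle counts toward a burst only if it passes all seven shape and
#' regularity criteria:
#' \describe{
#'   \item{A}{the negative peak is a local minimum of the raw signal;}
#'   \item{B}{the mean period to the neighbouring negative peaks lies inside
#'     the band's period range;}
#'   \item{C}{consecutive periods are similar: min/max ratio of the periods
#'     to the previous and next negative peak at least `period_ratio`;}
#'   \item{D}{rise and decay amplitudes have min/max ratio at least
#'     `rise_decay_ratio` (no flank under half the other at the default);}
#'   \item{E}{the cycle amplitude is similar to both neighbours: min/max
#'     ratio at least `amp_ratio` against each;}
#'   \item{F}{each flank moves in its expected direction for at least
#'     `mono_time` of its sample steps;}
#'   \item{G}{the net correctly-signed voltage change is at least `mono_amp`
#'     of the total voltage excursion, averaged over the two flanks.}
#' }
#' A burst requires `min_cycles` consecutive passing cycles.
#'
#' @param min_cycles Minimum run length of passing cycles (default 4).
#' @param period_ratio Criterion C threshold (default 0.6).
#' @param rise_decay_ratio Criterion D threshold (default 0.5).
#' @param amp_ratio Criterion E threshold (default 0.6).
#' @param mono_time Criterion F threshold (default 0.6).
#' @param mono_amp Criterion G threshold (default 0.6).
#' @return Object of class `criteria_thresholds`.
#' @export
criteria_thresholds <- function(min_cycles = 4L, period_ratio = 0.6,
                                rise_decay_ratio = 0.5, amp_ratio = 0.6,
                                mono_time = 0.6, mono_amp = 0.6) {
  ratios <- c(period_ratio, rise_decay_ratio, amp_ratio, mono_time, mono_amp)
  if (any(ratios <= 0 | ratios > 1))
    stop("criteria ratios must lie in (0, 1]")
  if (min_cycles < 2) stop("min_cycles must be at least 2")
  structure(list(min_cycles = as.integer(min_cycles),
                 period_ratio = period_ratio,
                 rise_decay_ratio = rise_decay_ratio,
                 amp_ratio = amp_ratio, mono_time = mono_time,
                 mono_amp = mono_amp),
            class = "criteria_thresholds")
}

.minmax_ratio <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (a == 0 && b == 0) return(1)
  mn <- min(a, b); mx <- max(a, b)
  if (mx == 0) return(1)
  mn / mx
}

#' Evaluate criteria A-G for every cycle
#'
#' Neighbour-dependent criteria (C, E) fail by definition when a neighbouring
#' cycle is missing (first/last cycle of a channel); criterion B uses the
#' mean of the available neighbour periods and fails when none exists.
#'
#' @param cycles A `cycle_frame` from [build_cycles()] or [parse_cycles()].
#' @param thresholds A [criteria_thresholds()].
#' @param band The [band_definition()] the cycles were parsed in.
#' @return Logical matrix, one row per cycle, columns `A`..`G`, plus
#'   attribute `pass` = row-wise conjunction.
#' @export
evaluate_criteria <- function(cycles, thresholds = criteria_thresholds(),
                              band) {
  stopifnot(is.data.frame(cycles), inherits(thresholds, "criteria_thresholds"),
            inherits(band, "band_definition"))
  n <- nrow(cycles)
  out <- matrix(FALSE, n, 7, dimnames = list(NULL, LETTERS[1:7]))
  if (n == 0L) {
    attr(out, "pass") <- logical(0)
    return(out)
  }
  prange <- band_period_range(band)
  vr <- function(a, b) {
    # vectorised min/max ratio; 0/0 counts as 1
    mn <- pmin(a, b); mx <- pmax(a, b)
    ifelse(is.na(mn), NA_real_, ifelse(mx == 0, 1, mn / mx))
  }
  out[, "A"] <- cycles$is_local_min %in% TRUE
  pp <- cycles$period_prev; pn <- cycles$period_next
  mp <- rowMeans(cbind(pp, pn), na.rm = TRUE)
  out[, "B"] <- !is.nan(mp) & !is.na(mp) & mp >= prange[1] & mp <= prange[2]
  cr <- vr(pp, pn)
  out[, "C"] <- !is.na(cr) & cr >= thresholds$period_ratio
  dr <- vr(cycles$rise_amp, cycles$decay_amp)
  out[, "D"] <- !is.na(dr) & dr >= thresholds$rise_decay_ratio
  amps <- cycles$amp
  e_prev <- c(NA_real_, vr(amps[-1], amps[-n]))
  e_next <- c(vr(amps[-n], amps[-1]), NA_real_)
  out[, "E"] <- !is.na(e_prev) & !is.na(e_next) &
    pmin(e_prev, e_next) >= thresholds$amp_ratio
  out[, "F"] <- cycles$mono_time_rise >= thresholds$mono_time &
    cycles$mono_time_decay >= thresholds$mono_time
  out[, "G"] <- cycles$mono_amp >= thresholds$mono_amp
  attr(out, "pass") <- rowSums(out) == 7L
  out
}

# collect a run of cycles into one burst record (internal)
.make_burst <- function(cycles, run_idx, fs_hz, channel, band_label,
                        polarity) {
  cy <- cycles[run_idx, , drop = FALSE]
  start <- min(cy$prev_pos); end <- max(cy$next_pos)
  negs <- sort(cy$neg)
  freq <- if (length(negs) >= 2L) 1 / mean(diff(negs) / fs_hz) else NA_real_
  list(channel = channel, band = band_label, polarity = polarity,
       start = start, end = end,
       start_s = (start - 1L) / fs_hz, end_s = (end - 1L) / fs_hz,
       n_cycles = nrow(cy), mean_freq = freq, mean_amp = mean(cy$amp),
       cycles = cy, fs_hz = fs_hz)
}

#' Form bursts from runs of criterion-passing cycles
#'
#' Maximal runs of consecutive cycles that pass all seven criteria and reach
#' the minimum run length become bursts; shorter runs are discarded. Cycles
#' flagged as touching the filter-edge region are treated as failing, so
#' transients never seed a burst.
#'
#' @param cycles A `cycle_frame`, time-ordered.
#' @param thresholds A [criteria_thresholds()].
#' @param band The [band_definition()].
#' @param fs_hz Sampling rate (Hz).
#' @param channel Channel index recorded on each burst.
#' @param polarity `"direct"` or `"inverted"`.
#' @return List of burst records (see [detect_channel_bursts()] for fields).
#' @export
detect_bursts <- function(cycles, thresholds = criteria_thresholds(), band,
                          fs_hz, channel = 1L, polarity = "direct") {
  crit <- evaluate_criteria(cycles, thresholds, band)
  pass <- attr(crit, "pass")
  if (!is.null(cycles$edge_ok)) pass <- pass & cycles$edge_ok
  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bursts <- list()
  for (k in seq_along(runs$values)) {
    if (runs$values[k] && runs$lengths[k] >= thresholds$min_cycles) {
      bursts[[length(bursts) + 1L]] <-
        .make_burst(cycles, starts[k]:ends[k], fs_hz, channel, band$label,
                    polarity)
    }
  }
  bursts
}

#' Detect bursts on both signal polarities
#'
#' Runs the full parse-and-detect pipeline on the signal and on its inverse;
#' rhythms with sharp troughs only (mu-like waveforms) are picked up on the
#' inverted trace. Duplicates from symmetric waveforms are handled later by
#' within-channel overlap resolution.
#'
#' @param raw Raw broadband signal (microvolts).
#' @param flt A `band_filter`.
#' @param thresholds A [criteria_thresholds()].
#' @param channel Channel index.
#' @return Combined list of burst records with `polarity` set.
#' @export
detect_dual_polarity <- function(raw, flt,
                                 thresholds = criteria_thresholds(),
                                 channel = 1L) {
  direct <- detect_bursts(parse_cycles(raw, flt), thresholds, flt$band,
                          flt$fs_hz, channel, "direct")
  inverted <- detect_bursts(parse_cycles(-raw, flt), thresholds, flt$band,
                            flt$fs_hz, channel, "inverted")
  c(direct, inverted)
}

# do two bursts overlap in time (half-open sample spans)?
.overlaps <- function(a, b) a$start < b$end && b$start < a$end

#' Resolve overlapping bursts within one channel
#'
#' Bursts from all bands and polarities of one channel are compared; the
#' largest (most cycles, ties broken by longer duration, then earlier start)
#' is retained intact and any overlapping competitor is trimmed to its
#' non-overlapping cycle runs. A trimmed remnant survives only if it still
#' holds the minimum cycle count. The result is pairwise non-overlapping.
#'
#' @param bursts List of burst records sharing one channel.
#' @param min_cycles Minimum cycles for a trimmed remnant to survive.
#' @return List of non-overlapping burst records.
#' @export
resolve_within_channel <- function(bursts, min_cycles = 4L) {
  kept <- list()
  pool <- bursts
  rank_key <- function(b) c(-b$n_cycles, -(b$end - b$start), b$start)
  while (length(pool) > 0L) {
    keys <- t(vapply(pool, rank_key, numeric(3)))
    ord <- order(keys[, 1], keys[, 2], keys[, 3])
    best <- pool[[ord[1]]]
    kept[[length(kept) + 1L]] <- best
    rest <- pool[ord[-1]]
    pool <- list()
    for (b in rest) {
      if (!.overlaps(b, best)) {
        pool[[length(pool) + 1L]] <- b
        next
      }
      # keep cycles whose own span [prev_pos, next_pos) clears the winner
      cy <- b$cycles
      clear <- cy$next_pos <= best$start | cy$prev_pos >= best$end
      runs <- rle(clear)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      for (k in seq_along(runs$values)) {
        if (runs$values[k] && runs$lengths[k] >= min_cycles) {
          pool[[length(pool) + 1L]] <-
            .make_burst(cy, starts[k]:ends[k], b$fs_hz, b$channel, b$band,
                        b$polarity)
        }
      }
    }
  }
  kept[order(vapply(kept, `[[`, 0, "start"))]
}
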