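#' Filter design specification for the narrowband filter bank
#'
#' Each band filter is a cascade of a high-pass and a low-pass linear-phase
#' equiripple FIR filter of minimum order: stopband edges sit 1 Hz outside the
#' passband edges, passband ripple is 0.04 dB (peak-to-peak) and stopband
#' attenuation 40 dB.
#'
#' @param transition_hz Transition width between passband and stopband edge,
#'   in Hz.
#' @param ripple_db Passband ripple, peak-to-peak, in dB.
#' @param atten_db Stopband attenuation in dB.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(transition_hz = 1, ripple_db = 0.04, atten_db = 40) {
  stopifnot(transition_hz > 0, ripple_db > 0, atten_db > 0)
  structure(list(transition_hz = transition_hz, ripple_db = ripple_db,
                 atten_db = atten_db),
            class = "filter_spec")
}

# linear ripple tolerances from the dB spec
.ripple_deltas <- function(spec) {
  r <- 10 ^ (spec$ripple_db / 20)
  list(dp = (r - 1) / (r + 1),           # passband deviation from 1
       ds = 10 ^ (-spec$atten_db / 20))  # stopband magnitude bound
}

# magnitude response of an FIR filter at frequencies f (Hz)
.fir_mag <- function(b, f, fs) {
  k <- seq_along(b) - 1
  vapply(f, function(fr) Mod(sum(b * exp(-2i * pi * fr / fs * k))), 0)
}

# Herrmann/Kaiser order estimate for an equiripple FIR transition
.order_estimate <- function(dp, ds, df_norm) {
  ceiling((-20 * log10(sqrt(dp * ds)) - 13) / (14.6 * df_norm))
}

# design one equiripple half (high- or low-pass) at minimum even order
.design_half <- function(fpass, fstop, fs, spec, type = c("high", "low")) {
  type <- match.arg(type)
  d <- .ripple_deltas(spec)
  nyq <- fs / 2
  df_norm <- abs(fpass - fstop) / fs
  if (type == "high") {
    f <- c(0, fstop, fpass, nyq) / nyq
    a <- c(0, 0, 1, 1)
    w <- c(d$dp / d$ds, 1)
  } else {
    f <- c(0, fpass, fstop, nyq) / nyq
    a <- c(1, 1, 0, 0)
    w <- c(1, d$dp / d$ds)
  }
  n <- max(10L, .order_estimate(d$dp, d$ds, df_norm))
  if (n %% 2L == 1L) n <- n + 1L  # even order: type-I FIR, integer delay
  grid <- sort(unique(c(seq(0, nyq, by = 0.05),
                        fpass, fstop, (fpass + fstop) / 2)))
  pass_f <- if (type == "high") grid[grid >= fpass] else grid[grid <= fpass]
  stop_f <- if (type == "high") grid[grid <= fstop] else grid[grid >= fstop]
  for (try in seq_len(200L)) {
    b <- tryCatch(signal::remez(n, f, a, w = w),
                  error = function(e) NULL)
    if (!is.null(b)) {
      hp <- .fir_mag(b, pass_f, fs)
      hs <- .fir_mag(b, stop_f, fs)
      if (max(abs(hp - 1)) <= d$dp && max(hs) <= d$ds)
        return(as.numeric(b))
    }
    n <- n + 2L
    if (n > 4000L) break
  }
  stop(sprintf(
    "cannot meet %s-pass spec (pass %g Hz, stop %g Hz) at fs = %g Hz",
    type, fpass, fstop, fs))
}

# design cache: filters are deterministic in (band, fs, spec)
.filter_cache <- new.env(parent = emptyenv())

#' Design the narrowband filter for one band
#'
#' Builds the high-pass-then-low-pass equiripple FIR cascade for a band at a
#' given sampling rate. Orders are found by iterative search upward from an
#' analytic estimate until the designed magnitude response meets the ripple
#' and attenuation specification; each designed response is audited
#' numerically and a violation is an error, never a silent pass.
#'
#' @param band A [band_definition()].
#' @param fs_hz Sampling rate in Hz; must exceed twice the upper stopband
#'   edge.
#' @param spec A [filter_spec()].
#' @return An object of class `band_filter`: list with the two coefficient
#'   vectors `b_high`, `b_low`, the integer group `delay` in samples, total
#'   effective length `n_edge` (samples at each end of a filtered signal that
#'   carry filter transients), plus `band`, `fs_hz` and `spec`.
#' @export
design_band_filter <- function(band, fs_hz, spec = filter_spec()) {
  stopifnot(inherits(band, "band_definition"), fs_hz > 0)
  tw <- spec$transition_hz
  if (tw >= band$high - band$low)
    stop("transition width must be smaller than the band width")
  if (fs_hz < 2 * (band$high + tw))
    stop(sprintf("fs = %g Hz too low for band %s (need >= %g Hz)",
                 fs_hz, band$label, 2 * (band$high + tw)))
  if (band$low - tw <= 0)
    stop("lower stopband edge must be positive")
  key <- sprintf("%s|%g|%g|%g|%g", band$label, fs_hz, tw, spec$ripple_db,
                 spec$atten_db)
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  b_high <- .design_half(band$low, band$low - tw, fs_hz, spec, "high")
  b_low <- .design_half(band$high, band$high + tw, fs_hz, spec, "low")
  delay <- (length(b_high) - 1L + length(b_low) - 1L) / 2L
  flt <- structure(
    list(b_high = b_high, b_low = b_low, delay = as.integer(delay),
         n_edge = as.integer(length(b_high) + length(b_low) - 2L),
         band = band, fs_hz = fs_hz, spec = spec),
    class = "band_filter")
  .filter_cache[[key]] <- flt
  flt
}

#' @export
print.band_filter <- function(x, ...) {
  cat(sprintf(
    "equiripple FIR cascade for band %s at fs %g Hz: HP %d taps, LP %d taps, delay %d samples\n",
    x$band$label, x$fs_hz, length(x$b_high), length(x$b_low), x$delay))
  invisible(x)
}

#' Apply a narrowband filter with group-delay compensation
#'
#' Filters a signal through the high-pass/low-pass cascade and shifts the
#' output back by the (integer) group delay so that zero-crossing times are
#' unbiased with respect to the input. Because both halves are symmetric
#' (linear-phase) FIRs, the shift restores exact zero phase in the passband
#' while preserving the designed magnitude response. The `n_edge` leading and
#' trailing samples contain filter transients; their index range is attached
#' as attribute `edge` and cycle parsing discards cycles that touch it.
#'
#' @param x Numeric signal vector (microvolts).
#' @param flt A `band_filter` from [design_band_filter()].
#' @return Filtered numeric vector, same length as `x`, with attribute
#'   `edge = c(first_reliable_index, last_reliable_index)` (1-based).
#' @export
apply_band_filter <- function(x, flt) {
  stopifnot(inherits(flt, "band_filter"), is.numeric(x))
  if (anyNA(x)) stop("signal contains NA")
  ntap <- length(flt$b_high) + length(flt$b_low) - 1L
  if (length(x) <= ntap)
    stop(sprintf("signal (%d samples) not longer than filter (%d taps)",
                 length(x), ntap))
  xp <- c(x, numeric(flt$delay))
  y <- stats::filter(xp, flt$b_high, method = "convolution", sides = 1)
  y[is.na(y)] <- 0
  y <- stats::filter(y, flt$b_low, method = "convolution", sides = 1)
  y[is.na(y)] <- 0
  y <- as.numeric(y)[(flt$delay + 1L):(flt$delay + length(x))]
  edge <- c(min(flt$n_edge + 1L, length(x)),
            max(1L, length(x) - flt$n_edge))
  attr(y, "edge") <- as.integer(edge)
  y
}

#' Broadband band-pass for minimally filtered EEG
#'
#' Zero-phase 0.5-40 Hz band-pass used as the preprocessing stage: peak
#' location runs on this minimally filtered signal, not on the narrowband
#' traces. Implemented by frequency-domain masking with raised-cosine
#' transitions (1 Hz wide), which is exactly zero-phase and transient-free.
#'
#' @param x Numeric signal vector.
#' @param fs_hz Sampling rate in Hz.
#' @param low,high Passband edges in Hz (defaults 0.5 and 40).
#' @param transition_hz Raised-cosine transition width (default 1).
#' @return Filtered numeric vector, same length.
#' @export
bandpass_broadband <- function(x, fs_hz, low = 0.5, high = 40,
                               transition_hz = 1) {
  stopifnot(is.numeric(x), fs_hz > 0, low >= 0, high > low)
  n <- length(x)
  f <- (seq_len(n) - 1) * fs_hz / n
  f <- pmin(f, fs_hz - f)  # two-sided axis
  ramp <- function(fr, edge, width) {
    # 0 below edge-width, 1 above edge, cosine in between
    v <- (fr - (edge - width)) / width
    ifelse(v <= 0, 0, ifelse(v >= 1, 1, 0.5 - 0.5 * cos(pi * v)))
  }
  mask <- ramp(f, low, min(low, transition_hz)) *
    (1 - ramp(f, high + transition_hz, transition_hz))
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}
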