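#' Welch power spectral density
#'
#' Averaged modified periodograms with Hann-tapered 8 s windows and 75%
#' overlap (0.125 Hz resolution at the defaults). Each segment is detrended
#' by its mean. One-sided density normalisation: the integral of the PSD over
#' frequency approximates the signal variance.
#'
#' @param x Numeric signal vector.
#' @param fs_hz Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 8).
#' @param overlap Fractional overlap between segments (default 0.75).
#' @return List with `freq_hz` and `psd` (microvolts^2 per Hz), class
#'   `welch_psd`.
#' @export
welch_psd <- function(x, fs_hz, window_s = 8, overlap = 0.75) {
  stopifnot(is.numeric(x), fs_hz > 0, window_s > 0, overlap >= 0,
            overlap < 1)
  nper <- round(window_s * fs_hz)
  if (length(x) < nper)
    stop(sprintf("signal (%d samples) shorter than one %g s window",
                 length(x), window_s))
  step <- max(1L, round(nper * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  u <- sum(w^2)
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs_hz * u)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1
  psd <- psd * dbl
  structure(list(freq_hz = (seq_len(nfreq) - 1L) * fs_hz / nper, psd = psd),
            class = "welch_psd")
}

#' @export
print.welch_psd <- function(x, ...) {
  cat(sprintf("Welch PSD: %d bins, 0-%.4g Hz, resolution %.4g Hz\n",
              length(x$freq_hz), max(x$freq_hz), x$freq_hz[2] - x$freq_hz[1]))
  invisible(x)
}

#' Pooled z-scoring of power spectra
#'
#' For each participant and frequency bin, power values are z-scored against
#' the pool of all sessions, conditions and channels of that participant
#' (sample standard deviation). This removes between-participant scale
#' differences (amplifier gain, skull thickness) while preserving relative
#' changes across sessions.
#'
#' @param spectra Data frame in long format with columns `participant`,
#'   `condition`, `session`, `channel`, `freq_hz`, `psd`.
#' @return The input with an added column `z`; pools with fewer than 2 values
#'   or zero spread yield `NA`.
#' @export
zscore_power <- function(spectra) {
  need <- c("participant", "condition", "session", "channel", "freq_hz",
            "psd")
  stopifnot(all(need %in% names(spectra)))
  key <- interaction(spectra$participant, spectra$freq_hz, drop = TRUE)
  spectra$z <- NA_real_
  for (k in levels(key)) {
    idx <- which(key == k)
    v <- spectra$psd[idx]
    if (length(v) >= 2L) {
      s <- stats::sd(v)
      if (is.finite(s) && s > 0) spectra$z[idx] <- (v - mean(v)) / s
    }
  }
  spectra
}

#' Outer-edge electrodes excluded from scalp averages
#'
#' Channel labels of the outermost ring of the 123-channel montage that are
#' dropped before averaging z-scored power across the scalp.
#'
#' @return Integer vector of channel labels.
#' @export
edge_channels <- function() c(48L, 63L, 68L, 73L, 81L, 88L, 94L, 99L, 119L)

#' Band-averaged z-scored power
#'
#' Averages z-scored power over retained channels (all minus an exclusion
#' list), then over the frequency bins inside the band (`[low, high)`),
#' giving one scalar per participant x session x condition.
#'
#' @param spectra Long-format data frame with a `z` column (see
#'   [zscore_power()]).
#' @param band A [band_definition()] (theta = 4-8, alpha = 8-12).
#' @param exclude Channel labels to drop; default [edge_channels()].
#' @return Data frame with columns `participant`, `condition`, `session`,
#'   `z_band`.
#' @export
band_average <- function(spectra, band, exclude = edge_channels()) {
  stopifnot("z" %in% names(spectra), inherits(band, "band_definition"))
  inband <- spectra$freq_hz >= band$low & spectra$freq_hz < band$high
  if (!any(inband))
    stop(sprintf("band %s outside the frequency axis", band$label))
  keep <- spectra[inband & !(spectra$channel %in% exclude), , drop = FALSE]
  # average channels within each frequency bin first, then bins
  agg1 <- stats::aggregate(
    z ~ participant + condition + session + freq_hz, data = keep,
    FUN = mean)
  agg2 <- stats::aggregate(z ~ participant + condition + session,
                           data = agg1, FUN = mean)
  names(agg2)[names(agg2) == "z"] <- "z_band"
  agg2
}
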