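#' Simulate 1/f aperiodic EEG background
#'
#' Spectrally shaped Gaussian noise: white noise is transformed to the
#' frequency domain, scaled by `f^(-exponent/2)` and transformed back, so the
#' power spectrum falls off with exactly the requested log-log slope and no
#' filter transients are introduced. `exponent = 0` gives white noise. Each
#' channel is scaled to the requested standard deviation in microvolts.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param fs_hz Sampling rate in Hz (>= 100).
#' @param exponent Aperiodic exponent (power ~ 1/f^exponent).
#' @param scale_uV Per-channel standard deviation in microvolts.
#' @param n_channels Number of channels.
#' @param seed Integer seed; the output is a pure function of it.
#' @return Object of class `eeg_sim`: list with `signal` (samples x channels
#'   matrix, microvolts), `fs_hz`, `duration_s`.
#' @export
gen_aperiodic_eeg <- function(duration_s, fs_hz, exponent = 1,
                              scale_uV = 10, n_channels = 1L, seed = NULL) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs_hz < 100) stop("fs_hz must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs_hz)
  freqs <- c(0, seq_len(n - 1)) * fs_hz / n
  # fold to two-sided axis; DC gets zero amplitude
  f2 <- pmin(freqs, fs_hz - freqs)
  shape <- c(0, f2[-1] ^ (-exponent / 2))
  sig <- matrix(0, n, n_channels)
  for (ch in seq_len(n_channels)) {
    white <- stats::rnorm(n)
    shaped <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / n
    sig[, ch] <- shaped / stats::sd(shaped) * scale_uV
  }
  structure(list(signal = sig, fs_hz = fs_hz, duration_s = n / fs_hz),
            class = "eeg_sim")
}

# asymmetric sinusoid: one "cycle" runs positive peak -> negative peak ->
# positive peak; the descending flank occupies fraction `r` of the period
.burst_wave <- function(t_rel, freq, amp_pp, r = 0.5) {
  u <- freq * t_rel - 0.25
  xi <- u - floor(u)                 # position within a descending-start period
  theta <- ifelse(xi < r, 0.25 + 0.5 * xi / r,
                  0.75 + 0.5 * (xi - r) / (1 - r))
  amp_pp / 2 * sin(2 * pi * theta)
}

#' Insert oscillation bursts with ground truth into a background
#'
#' Each requested burst is an added sinusoid (optionally flank-asymmetric)
#' of known frequency, peak-to-peak amplitude and cycle count. The emitted
#' waveform carries one sacrificial lead-in and lead-out cycle beyond the
#' nominal count: those edge cycles deterministically fail the
#' neighbour-similarity criteria (their neighbours are the on/off ramps of
#' the sine), while giving every nominal cycle full neighbour context. The
#' ground-truth table records the nominal cycles, which is exactly what the
#' detector recovers on a noise-free background.
#'
#' @param background An `eeg_sim` (or samples x channels matrix with
#'   `fs_hz` supplied).
#' @param specs Data frame with columns `channel`, `freq_hz`, `n_cycles`
#'   (nominal, >= 4), `amp_uV` (peak-to-peak), `onset_s` (waveform start).
#' @param asymmetry Fraction of each period spent on the descending flank
#'   (default 0.5 = symmetric; values far from 0.5 emulate mu-like sharp
#'   troughs on one polarity).
#' @param fs_hz Sampling rate, only needed when `background` is a bare
#'   matrix.
#' @return List with `signal` (an `eeg_sim`) and `truth`: data frame
#'   `channel`, `band`, `onset_s` (start of the recoverable span), `n_cycles`,
#'   `amp_uV`, `freq_hz`, plus `wave_onset_s`, `wave_dur_s` for the full
#'   emitted waveform.
#' @export
insert_bursts <- function(background, specs, asymmetry = 0.5, fs_hz = NULL) {
  if (inherits(background, "eeg_sim")) {
    sig <- background$signal
    fs_hz <- background$fs_hz
  } else {
    sig <- as.matrix(background)
    if (is.null(fs_hz)) stop("fs_hz required for a bare matrix background")
  }
  if (is.null(specs) || nrow(specs) == 0L) {
    return(list(signal = structure(list(signal = sig, fs_hz = fs_hz,
                                        duration_s = nrow(sig) / fs_hz),
                                   class = "eeg_sim"),
                truth = data.frame()))
  }
  stopifnot(all(c("channel", "freq_hz", "n_cycles", "amp_uV", "onset_s")
                %in% names(specs)),
            all(specs$n_cycles >= 4), all(specs$amp_uV > 0),
            asymmetry > 0, asymmetry < 1)
  n <- nrow(sig)
  specs$wave_dur_s <- (specs$n_cycles + 2) / specs$freq_hz
  # reject overlaps within a channel and out-of-range placements
  for (ch in unique(specs$channel)) {
    s <- specs[specs$channel == ch, , drop = FALSE]
    s <- s[order(s$onset_s), , drop = FALSE]
    if (nrow(s) > 1L &&
        any(s$onset_s[-1] < (s$onset_s + s$wave_dur_s)[-nrow(s)]))
      stop(sprintf("overlapping burst specs in channel %s", ch))
  }
  if (any(specs$onset_s < 0 |
          specs$onset_s + specs$wave_dur_s > n / fs_hz))
    stop("burst specs must fit inside the recording")
  truth <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    i0 <- round(sp$onset_s * fs_hz) + 1L
    i1 <- min(n, i0 + round(sp$wave_dur_s * fs_hz) - 1L)
    idx <- i0:i1
    t_rel <- (idx - i0) / fs_hz
    sig[idx, sp$channel] <- sig[idx, sp$channel] +
      .burst_wave(t_rel, sp$freq_hz, sp$amp_uV, asymmetry)
    # recoverable span: nominal cycles start after the lead-in cycle
    truth[[i]] <- data.frame(
      channel = sp$channel, band = band_assign(sp$freq_hz),
      onset_s = sp$onset_s + 1.25 / sp$freq_hz,
      n_cycles = as.integer(sp$n_cycles), amp_uV = sp$amp_uV,
      freq_hz = sp$freq_hz, wave_onset_s = sp$onset_s,
      wave_dur_s = sp$wave_dur_s)
  }
  list(signal = structure(list(signal = sig, fs_hz = fs_hz,
                               duration_s = n / fs_hz), class = "eeg_sim"),
       truth = do.call(rbind, truth))
}

#' Generate an auditory oddball tone sequence
#'
#' 160 standards and 40 targets by default, inter-onset intervals uniform on
#' 1.8-2.4 s, and at least 3 standards between consecutive targets. The
#' excess standards beyond the guaranteed gaps are distributed at random
#' over the gap slots (before the first target, between targets, after the
#' last).
#'
#' @param n_standard Number of standard tones (default 160).
#' @param n_target Number of target tones (default 40).
#' @param isi_min,isi_max Inter-onset interval bounds in seconds
#'   (defaults 1.8, 2.4).
#' @param min_gap Minimum standards between consecutive targets (default 3).
#' @param seed Integer seed.
#' @return Data frame `onset_s`, `type` (`"standard"`/`"target"`), first
#'   onset at 0.
#' @export
gen_oddball_sequence <- function(n_standard = 160L, n_target = 40L,
                                 isi_min = 1.8, isi_max = 2.4,
                                 min_gap = 3L, seed = NULL) {
  stopifnot(n_standard >= 0, n_target >= 0, isi_min > 0, isi_max >= isi_min)
  need <- min_gap * max(0L, n_target - 1L)
  if (n_standard < need)
    stop(sprintf(
      "infeasible: %d standards cannot give %d gaps of >= %d",
      n_standard, n_target - 1L, min_gap))
  if (!is.null(seed)) set.seed(seed)
  n_slots <- n_target + 1L
  gaps <- c(0L, rep(as.integer(min_gap), max(0L, n_target - 1L)), 0L)
  if (n_target == 0L) gaps <- n_standard
  else {
    excess <- n_standard - need
    if (excess > 0L)
      gaps <- gaps + tabulate(sample.int(n_slots, excess, replace = TRUE),
                              n_slots)
  }
  type <- character(0)
  for (k in seq_len(length(gaps))) {
    type <- c(type, rep("standard", gaps[k]))
    if (k <= n_target) type <- c(type, "target")
  }
  n_tones <- length(type)
  isi <- stats::runif(max(0L, n_tones - 1L), isi_min, isi_max)
  data.frame(onset_s = c(0, cumsum(isi)), type = type)
}

#' Simulate a pupil trace with ground-truth closures
#'
#' Constant baseline diameter plus optional white noise and event-locked
#' dilations (gamma-shaped kernel peaking at 0.9 s). Blinks (uniform 0.1-0.6
#' s) occur at a Poisson rate; ocular microsleeps are 2 s closures whose
#' count is set to hit the requested closed-time fraction. Closures are
#' encoded as confidence drops below 0.5 and snapped to the sample grid so
#' that closure detection can recover the ground truth exactly. Diameter is
#' reported in pixels under a known iris calibration so the
#' pixel-to-millimetre conversion is checkable.
#'
#' @param duration_s Recording duration (s).
#' @param fs_hz Analysis sampling rate (default 50).
#' @param baseline_mm Baseline pupil diameter in millimetres.
#' @param blink_rate_per_min Expected blinks per minute (>= 0).
#' @param microsleep_fraction Fraction of time in microsleeps (in [0, 1)).
#' @param event_responses Optional data frame `onset_s`, `amp_mm` of
#'   event-locked dilations.
#' @param noise_sd Diameter noise SD in millimetres.
#' @param seed Integer seed.
#' @return List with `trace` (`time_s`, `diameter_px`, `confidence`),
#'   `closures` (`start_s`, `duration_s`, `kind`), `calibration` (an
#'   [iris_calibration()]), `baseline_mm`.
#' @export
gen_pupil_trace <- function(duration_s, fs_hz = 50, baseline_mm = 4,
                            blink_rate_per_min = 10,
                            microsleep_fraction = 0,
                            event_responses = NULL, noise_sd = 0,
                            seed = NULL) {
  if (blink_rate_per_min < 0 || noise_sd < 0)
    stop("rates and noise must be non-negative")
  if (microsleep_fraction < 0 || microsleep_fraction >= 1)
    stop("microsleep_fraction must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs_hz)
  time_s <- (seq_len(n) - 1) / fs_hz
  cal <- iris_calibration(iris_cm = 1.2)
  mm <- rep(baseline_mm, n)
  if (noise_sd > 0) mm <- mm + stats::rnorm(n, 0, noise_sd)
  if (!is.null(event_responses) && nrow(event_responses) > 0) {
    for (i in seq_len(nrow(event_responses))) {
      t0 <- event_responses$onset_s[i]
      rel <- time_s - t0
      k <- ifelse(rel > 0, (rel / 0.9) * exp(1 - rel / 0.9), 0)
      mm <- mm + event_responses$amp_mm[i] * k
    }
  }
  # ground-truth closures, snapped to whole samples, non-overlapping
  n_blinks <- stats::rpois(1, blink_rate_per_min * duration_s / 60)
  blink_len <- pmax(3L, round(stats::runif(n_blinks, 0.1, 0.6) * fs_hz))
  ms_len_samp <- round(2 * fs_hz)
  n_ms <- round(microsleep_fraction * n / ms_len_samp)
  lens <- c(blink_len, rep(ms_len_samp, n_ms))
  kinds <- c(rep("blink", n_blinks), rep("microsleep", n_ms))
  occupied <- rep(FALSE, n)
  starts <- integer(0); durs <- integer(0); out_kind <- character(0)
  ord <- order(-lens)  # place long closures first
  for (j in ord) {
    len <- lens[j]
    placed <- FALSE
    for (try in seq_len(200L)) {
      s0 <- sample.int(max(1L, n - len - 3L), 1L)
      span <- max(1L, s0 - 3L):min(n, s0 + len + 2L)  # 3-sample guard band
      if (!any(occupied[span])) {
        occupied[s0:(s0 + len - 1L)] <- TRUE
        starts <- c(starts, s0); durs <- c(durs, len)
        out_kind <- c(out_kind, kinds[j])
        placed <- TRUE
        break
      }
    }
    if (!placed) warning("could not place a closure without overlap")
  }
  conf <- rep(0.95, n)
  closed <- rep(FALSE, n)
  for (j in seq_along(starts))
    closed[starts[j]:(starts[j] + durs[j] - 1L)] <- TRUE
  conf[closed] <- 0.15
  ordj <- order(starts)
  closures <- data.frame(start_s = (starts[ordj] - 1L) / fs_hz,
                         duration_s = durs[ordj] / fs_hz,
                         kind = out_kind[ordj])
  px <- mm * cal$iris_cm * cal$video_width_px /
    (cal$video_width_cm * cal$standard_iris_mm)
  list(trace = data.frame(time_s = time_s, diameter_px = px,
                          confidence = conf),
       closures = closures, calibration = cal, baseline_mm = baseline_mm)
}

#' Configuration for a simulated extended-wake study
#'
#' Session-level outcome trajectories: oscillation amplitude follows an
#' increasing saturating exponential of time awake (sleep-homeostatic
#' build-up) with a dip during the wake-maintenance-zone sessions S6 and S7;
#' oscillation quantity follows a linear trend. Gaussian noise is added per
#' participant and session.
#'
#' @param n_participants Number of simulated participants (default 18).
#' @param schedule Named clock times (decimal h) for S1..S8; default
#'   [session_schedule()].
#' @param wake_h Clock time at which the extended wake period starts
#'   (default 2.5, i.e. 4 h after a 22:30 habitual bedtime).
#' @param asymptote Saturating-exponential asymptote (z units).
#' @param rate Exponential rate per hour awake.
#' @param wmz_dip Dip subtracted at S6 and S7 (z units, >= 0 dips down).
#' @param quantity_slope Linear slope of the quantity outcome per hour.
#' @param noise_sd Between-session noise SD.
#' @param seed Integer seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_participants = 18L, schedule = session_schedule(),
                         wake_h = 2.5, asymptote = 2, rate = 0.15,
                         wmz_dip = 1, quantity_slope = 0.08, noise_sd = 0.5,
                         seed = NULL) {
  stopifnot(n_participants >= 1, noise_sd >= 0)
  if (any(diff(schedule) <= 0))
    stop("schedule times must be strictly ordered within the wake period")
  structure(list(n_participants = as.integer(n_participants),
                 schedule = schedule, wake_h = wake_h,
                 asymptote = asymptote, rate = rate, wmz_dip = wmz_dip,
                 quantity_slope = quantity_slope, noise_sd = noise_sd,
                 seed = seed),
            class = "study_config")
}

#' Simulate per-session outcomes for an extended-wake study
#'
#' @param config A [study_config()].
#' @return List with `table` (long `SessionTable`: `participant`,
#'   `condition`, `session`, `clock_h`, `outcome`, `value`), `wide` (list of
#'   participants x sessions matrices per outcome) and `params` (the true
#'   generating parameters).
#' @export
gen_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sess <- names(config$schedule)
  awake <- config$schedule - config$wake_h
  np <- config$n_participants
  ns <- length(sess)
  dipvec <- ifelse(sess %in% c("S6", "S7"), config$wmz_dip, 0)
  mk <- function(base) {
    m <- matrix(rep(base, each = np), np, ns,
                dimnames = list(sprintf("P%02d", seq_len(np)), sess))
    m + matrix(stats::rnorm(np * ns, 0, config$noise_sd), np, ns)
  }
  amp_base <- config$asymptote * (1 - exp(-config$rate * awake)) - dipvec
  qty_base <- config$quantity_slope * awake - dipvec
  wide <- list(amplitude = mk(amp_base), quantity = mk(qty_base))
  long <- do.call(rbind, lapply(names(wide), function(oc) {
    m <- wide[[oc]]
    data.frame(participant = rep(rownames(m), ns),
               condition = "Fixation",
               session = rep(sess, each = np),
               clock_h = rep(unname(config$schedule), each = np),
               outcome = oc, value = as.vector(m))
  }))
  list(table = long, wide = wide,
       params = config[c("asymptote", "rate", "wmz_dip", "quantity_slope",
                         "noise_sd")])
}
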