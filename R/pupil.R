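#' Detect eye-closures from pupil-model confidence
#'
#' Timepoints with model confidence below the threshold are eyes-closed.
#' Hysteresis is applied in the order stated by the rule: confident spans
#' shorter than the hysteresis window that interrupt a closure remain
#' eyes-closed (closure merging first), then below-threshold dips shorter
#' than the window inside open periods remain open. Uses the confidence
#' series only, never the diameter.
#'
#' @param confidence Numeric vector in `[0, 1]`, uniformly sampled.
#' @param fs_hz Sampling rate in Hz (analysis rate 50 Hz).
#' @param threshold Confidence below which the eye counts as closed
#'   (default 0.5).
#' @param hysteresis_s Minimum duration for a state flip to stand
#'   (default 0.05 s).
#' @return Data frame of closure events: `start_s`, `duration_s`,
#'   `start_idx`, `end_idx` (half-open sample span).
#' @export
detect_closures <- function(confidence, fs_hz = 50, threshold = 0.5,
                            hysteresis_s = 0.05) {
  stopifnot(is.numeric(confidence), fs_hz > 0)
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop("confidence must lie in [0, 1]")
  closed <- confidence < threshold
  closed[is.na(closed)] <- TRUE
  flip_short <- function(state, value, min_len, interior_only) {
    runs <- rle(state)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      if (runs$values[k] != value) next
      if (runs$lengths[k] >= min_len) next
      if (interior_only && (k == 1L || k == length(runs$values))) next
      state[starts[k]:ends[k]] <- !value
    }
    state
  }
  min_len <- ceiling(hysteresis_s * fs_hz)
  # short confident interruptions of a closure stay closed...
  closed <- flip_short(closed, FALSE, min_len, interior_only = TRUE)
  # ...then short isolated dips stay open
  closed <- flip_short(closed, TRUE, min_len, interior_only = FALSE)
  runs <- rle(closed)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  sel <- which(runs$values)
  data.frame(start_s = (starts[sel] - 1L) / fs_hz,
             duration_s = runs$lengths[sel] / fs_hz,
             start_idx = starts[sel], end_idx = ends[sel] + 1L)
}

#' Classify closures into blinks and ocular microsleeps
#'
#' Closures shorter than 1 s are blinks; closures of 1 s or longer are
#' ocular microsleeps.
#'
#' @param events Closure table from [detect_closures()].
#' @param duration_s Recording duration in seconds (for rates).
#' @param cutoff_s Blink/microsleep boundary (default 1 s).
#' @return List with `events` (input plus a `kind` column), `blink_rate_min`
#'   (blinks per minute), `microsleep_fraction` (fraction of recording time
#'   spent in microsleeps), `n_blinks`, `n_microsleeps`.
#' @export
classify_closures <- function(events, duration_s, cutoff_s = 1) {
  stopifnot(duration_s > 0)
  kind <- ifelse(events$duration_s < cutoff_s, "blink", "microsleep")
  events$kind <- if (nrow(events)) kind else character(0)
  list(events = events,
       blink_rate_min = sum(kind == "blink") / (duration_s / 60),
       microsleep_fraction =
         sum(events$duration_s[kind == "microsleep"]) / duration_s,
       n_blinks = sum(kind == "blink"),
       n_microsleeps = sum(kind == "microsleep"))
}

#' Iris-based pixel-to-millimetre calibration
#'
#' The eye-camera frame has a known size in pixels and centimetres; the
#' iris diameter is measured in centimetres on a selected frame and mapped
#' to the human mean iris diameter of 12 mm, giving a conversion factor for
#' all 2D pupil diameters of that recording.
#'
#' @param video_width_px Frame width in pixels (default 192).
#' @param video_width_cm Frame width in centimetres (default 4.5).
#' @param iris_cm Measured iris diameter in centimetres.
#' @param standard_iris_mm Reference human iris diameter (default 12 mm).
#' @return Object of class `iris_calibration`.
#' @export
iris_calibration <- function(iris_cm, video_width_px = 192,
                             video_width_cm = 4.5, standard_iris_mm = 12) {
  if (any(c(iris_cm, video_width_px, video_width_cm, standard_iris_mm) <= 0))
    stop("all calibration fields must be positive")
  structure(list(video_width_px = video_width_px,
                 video_width_cm = video_width_cm, iris_cm = iris_cm,
                 standard_iris_mm = standard_iris_mm),
            class = "iris_calibration")
}

#' Convert pupil diameter from pixels to millimetres
#'
#' `mm = px * width_cm * standard_iris_mm / (iris_cm * width_px)`.
#'
#' @param diameter_px Numeric vector of pupil diameters in pixels.
#' @param cal An [iris_calibration()].
#' @return Diameters in millimetres.
#' @export
px_to_mm <- function(diameter_px, cal) {
  stopifnot(inherits(cal, "iris_calibration"))
  diameter_px * cal$video_width_cm * cal$standard_iris_mm /
    (cal$iris_cm * cal$video_width_px)
}

#' Clean a pupil trace: interpolate short gaps, drop short islands
#'
#' Invalid stretches (eyes-closed / low confidence) shorter than 0.5 s are
#' linearly interpolated between their valid endpoints; afterwards, isolated
#' valid islands shorter than 0.5 s are removed. The pass order is fixed:
#' interpolation first, island removal second.
#'
#' @param diameter Numeric vector (px or mm); invalid samples may be `NA`.
#' @param valid Logical vector marking valid samples (e.g. eyes-open from
#'   [detect_closures()]).
#' @param fs_hz Sampling rate in Hz.
#' @param max_gap_s Maximum gap length to interpolate (default 0.5 s).
#' @param min_island_s Minimum surviving island length (default 0.5 s).
#' @return List with `diameter` (`NA` where removed) and `valid` (updated
#'   mask). A fully invalid trace comes back all-`NA` with a warning.
#' @export
clean_trace <- function(diameter, valid, fs_hz = 50, max_gap_s = 0.5,
                        min_island_s = 0.5) {
  stopifnot(length(diameter) == length(valid), fs_hz > 0)
  n <- length(diameter)
  if (!any(valid)) {
    warning("trace entirely invalid; returning empty")
    return(list(diameter = rep(NA_real_, n), valid = rep(FALSE, n)))
  }
  d <- diameter
  d[!valid] <- NA
  v <- valid
  runs <- rle(v)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  # pass 1: linear interpolation of short interior gaps
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) next
    if (runs$lengths[k] / fs_hz >= max_gap_s) next
    if (k == 1L || k == length(runs$values)) next  # no anchor at the ends
    a <- starts[k] - 1L; b <- ends[k] + 1L
    idx <- starts[k]:ends[k]
    d[idx] <- d[a] + (d[b] - d[a]) * (idx - a) / (b - a)
    v[idx] <- TRUE
  }
  # pass 2: drop isolated valid islands shorter than the minimum
  runs <- rle(v)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    if (runs$lengths[k] / fs_hz >= min_island_s) next
    idx <- starts[k]:ends[k]
    d[idx] <- NA
    v[idx] <- FALSE
  }
  list(diameter = d, valid = v)
}

#' Resample a pupil trace onto a uniform analysis grid
#'
#' Linear interpolation from the (possibly jittery ~120 Hz) acquisition
#' timestamps onto a uniform grid at the analysis rate. Confidence is
#' interpolated with constant (nearest-previous) steps so closure spans are
#' preserved.
#'
#' @param time_s Acquisition timestamps (strictly increasing).
#' @param diameter_px Diameters at `time_s`.
#' @param confidence Confidences at `time_s`.
#' @param fs_out Output rate in Hz (default 50).
#' @return Data frame `time_s`, `diameter_px`, `confidence` on the uniform
#'   grid.
#' @export
resample_trace <- function(time_s, diameter_px, confidence, fs_out = 50) {
  stopifnot(all(diff(time_s) > 0))
  grid <- seq(time_s[1], time_s[length(time_s)], by = 1 / fs_out)
  data.frame(
    time_s = grid,
    diameter_px = stats::approx(time_s, diameter_px, grid, rule = 2)$y,
    confidence = stats::approx(time_s, confidence, grid, method = "constant",
                               rule = 2)$y)
}
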