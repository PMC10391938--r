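#' Epoch and average pupil responses to oddball tones for one session
#'
#' Epochs the cleaned trace from -0.5 to 2 s around each tone onset. All
#' targets are used, together with the standard immediately preceding each
#' target. Each trial is baseline-corrected by its mean over -0.5 to 0 s.
#' Trials with fewer than 2/3 clean timepoints are excluded; a session is
#' unusable when either tone type retains fewer than `min_trials` trials, or
#' when any averaged timepoint would pool fewer than `min_per_timepoint`
#' trials.
#'
#' @param time_s Uniform time axis of the cleaned trace (s).
#' @param diameter Cleaned diameter (NA where removed).
#' @param events Data frame with `onset_s` and `type`
#'   (`"standard"`/`"target"`).
#' @param fs_hz Sampling rate (default 50).
#' @param epoch_s Epoch window, seconds relative to onset
#'   (default `c(-0.5, 2)`).
#' @param min_clean_frac Minimum fraction of non-NA samples per trial
#'   (default 2/3).
#' @param min_trials Minimum usable trials per tone type (default 15).
#' @param min_per_timepoint Minimum trials behind each averaged timepoint
#'   (default 10).
#' @return List with `usable` (logical), `reason` (character, when not
#'   usable), `rel_time_s`, `target` and `standard` averaged courses,
#'   `n_target`, `n_standard` trial counts.
#' @export
oddball_session <- function(time_s, diameter, events, fs_hz = 50,
                            epoch_s = c(-0.5, 2), min_clean_frac = 2 / 3,
                            min_trials = 15, min_per_timepoint = 10) {
  stopifnot(length(time_s) == length(diameter))
  tgt_idx <- which(events$type == "target")
  std_before <- vapply(tgt_idx, function(i) {
    prev <- which(events$type == "standard" & events$onset_s < events$onset_s[i])
    if (length(prev)) prev[length(prev)] else NA_integer_
  }, 0L)
  std_idx <- std_before[!is.na(std_before)]
  rel <- seq(epoch_s[1], epoch_s[2], by = 1 / fs_hz)
  nbin <- length(rel)
  base_win <- rel >= epoch_s[1] & rel < 0
  epoch_one <- function(onset) {
    samp <- round((onset + rel - time_s[1]) * fs_hz) + 1L
    if (samp[1] < 1L || samp[nbin] > length(diameter))
      return(NULL)
    y <- diameter[samp]
    if (mean(!is.na(y)) < min_clean_frac) return(NULL)
    y - mean(y[base_win], na.rm = TRUE)
  }
  collect <- function(idx) {
    tr <- lapply(events$onset_s[idx], epoch_one)
    do.call(rbind, tr[!vapply(tr, is.null, TRUE)])
  }
  tgt <- collect(tgt_idx)
  std <- collect(std_idx)
  fail <- function(reason)
    list(usable = FALSE, reason = reason, rel_time_s = rel,
         target = NULL, standard = NULL,
         n_target = if (is.null(tgt)) 0L else nrow(tgt),
         n_standard = if (is.null(std)) 0L else nrow(std))
  if (is.null(tgt) || nrow(tgt) < min_trials)
    return(fail(sprintf("fewer than %d usable target trials", min_trials)))
  if (is.null(std) || nrow(std) < min_trials)
    return(fail(sprintf("fewer than %d usable standard trials", min_trials)))
  n_per_t <- colSums(!is.na(tgt)); n_per_s <- colSums(!is.na(std))
  if (any(n_per_t < min_per_timepoint) || any(n_per_s < min_per_timepoint))
    return(fail(sprintf("a timepoint pools fewer than %d trials",
                        min_per_timepoint)))
  list(usable = TRUE, reason = NA_character_, rel_time_s = rel,
       target = colMeans(tgt, na.rm = TRUE),
       standard = colMeans(std, na.rm = TRUE),
       n_target = nrow(tgt), n_standard = nrow(std))
}

#' Pupillary oddball response across a participant's sessions
#'
#' Collects the per-session averaged target and standard courses, drops the
#' participant when fewer than `min_sessions` of the scheduled recordings
#' are usable, z-scores the averaged courses within the participant (pooling
#' timepoints, tone types and sessions), and quantifies each session's
#' response as the trapezoidal area under the target-minus-standard
#' difference between 0.5 and 2 s (z units x s).
#'
#' @param sessions Named list of [oddball_session()] results (one per
#'   scheduled recording).
#' @param min_sessions Minimum usable sessions to keep the participant
#'   (default 6).
#' @param auc_window Integration window in seconds (default `c(0.5, 2)`).
#' @return List with `usable`, `reason`, and when usable a data frame
#'   `responses` (`session`, `auc_z_s`, `n_target`, `n_standard`) plus the
#'   z-scored courses in `courses`.
#' @export
oddball_response <- function(sessions, min_sessions = 6,
                             auc_window = c(0.5, 2)) {
  if (is.null(names(sessions)))
    names(sessions) <- sprintf("S%d", seq_along(sessions))
  ok <- vapply(sessions, function(s) isTRUE(s$usable), TRUE)
  if (sum(ok) < min_sessions)
    return(list(usable = FALSE,
                reason = sprintf("only %d of %d sessions usable (minimum %d)",
                                 sum(ok), length(sessions), min_sessions),
                responses = NULL, courses = NULL))
  keep <- sessions[ok]
  pool <- unlist(lapply(keep, function(s) c(s$target, s$standard)))
  mu <- mean(pool); sdv <- stats::sd(pool)
  if (!is.finite(sdv) || sdv == 0)
    return(list(usable = FALSE, reason = "zero pooled spread",
                responses = NULL, courses = NULL))
  courses <- lapply(keep, function(s) {
    s$target <- (s$target - mu) / sdv
    s$standard <- (s$standard - mu) / sdv
    s
  })
  responses <- do.call(rbind, lapply(names(courses), function(nm) {
    s <- courses[[nm]]
    rel <- s$rel_time_s
    win <- rel >= auc_window[1] & rel <= auc_window[2]
    diff_c <- (s$target - s$standard)[win]
    tt <- rel[win]
    auc <- sum(diff(tt) * (utils::head(diff_c, -1) + utils::tail(diff_c, -1)) / 2)
    data.frame(session = nm, auc_z_s = auc, n_target = s$n_target,
               n_standard = s$n_standard)
  }))
  list(usable = TRUE, reason = NA_character_, responses = responses,
       courses = courses)
}
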