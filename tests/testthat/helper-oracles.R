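# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations.

# peaks: exhaustive argmin/argmax per half-open crossing span
oracle_locate_peaks <- function(raw, crossings) {
  ev <- data.frame(
    at = c(crossings$descending, crossings$rising),
    kind = c(rep("desc", length(crossings$descending)),
             rep("rise", length(crossings$rising))))
  ev <- ev[order(ev$at), , drop = FALSE]
  idx <- integer(0); kind <- character(0)
  if (nrow(ev) < 2) return(data.frame(index = idx, kind = kind))
  for (i in 1:(nrow(ev) - 1)) {
    span <- ev$at[i]:(ev$at[i + 1] - 1)
    if (length(span) < 1) next
    if (ev$kind[i] == "desc") {
      best <- span[1]
      for (s in span) if (raw[s] < raw[best]) best <- s
      idx <- c(idx, best); kind <- c(kind, "neg")
    } else {
      best <- span[1]
      for (s in span) if (raw[s] > raw[best]) best <- s
      idx <- c(idx, best); kind <- c(kind, "pos")
    }
  }
  data.frame(index = idx, kind = kind)
}

# per-cycle features recomputed sample by sample
oracle_cycle_features <- function(p0, ng, p1, raw, fs) {
  rise <- raw[p0] - raw[ng]
  decay <- raw[p1] - raw[ng]
  down <- raw[p0:ng]; up <- raw[ng:p1]
  frac_dir <- function(seg, dir) {
    d <- diff(seg)
    if (length(d) == 0) return(1)
    ok <- 0
    for (v in d) if ((dir == "down" && v < 0) || (dir == "up" && v > 0))
      ok <- ok + 1
    ok / length(d)
  }
  net_frac <- function(seg, dir) {
    d <- diff(seg)
    tot <- sum(abs(d))
    if (tot == 0) return(1)
    net <- if (dir == "down") -sum(d) else sum(d)
    min(1, max(0, net / tot))
  }
  list(rise = rise, decay = decay, amp = (rise + decay) / 2,
       mt_rise = frac_dir(down, "down"), mt_decay = frac_dir(up, "up"),
       ma = (net_frac(down, "down") + net_frac(up, "up")) / 2,
       local_min = ng > 1 && ng < length(raw) &&
         raw[ng] <= raw[ng - 1] && raw[ng] <= raw[ng + 1])
}

# criteria A-G per cycle, plain row loop
oracle_criteria <- function(cyc, th, prange) {
  n <- nrow(cyc)
  out <- matrix(FALSE, n, 7, dimnames = list(NULL, LETTERS[1:7]))
  mmr <- function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    if (max(a, b) == 0) return(1)
    min(a, b) / max(a, b)
  }
  for (i in seq_len(n)) {
    out[i, 1] <- isTRUE(cyc$is_local_min[i])
    ps <- c(cyc$period_prev[i], cyc$period_next[i])
    mp <- if (all(is.na(ps))) NA else mean(ps, na.rm = TRUE)
    out[i, 2] <- !is.na(mp) && mp >= prange[1] && mp <= prange[2]
    r <- mmr(cyc$period_prev[i], cyc$period_next[i])
    out[i, 3] <- !is.na(r) && r >= th$period_ratio
    r <- mmr(cyc$rise_amp[i], cyc$decay_amp[i])
    out[i, 4] <- !is.na(r) && r >= th$rise_decay_ratio
    ep <- if (i > 1) mmr(cyc$amp[i], cyc$amp[i - 1]) else NA
    en <- if (i < n) mmr(cyc$amp[i], cyc$amp[i + 1]) else NA
    out[i, 5] <- !is.na(ep) && !is.na(en) && min(ep, en) >= th$amp_ratio
    out[i, 6] <- cyc$mono_time_rise[i] >= th$mono_time &&
      cyc$mono_time_decay[i] >= th$mono_time
    out[i, 7] <- cyc$mono_amp[i] >= th$mono_amp
  }
  out
}

# maximal runs of TRUE with length >= minlen, explicit scan
oracle_runs <- function(pass, minlen) {
  runs <- list(); start <- NA
  for (i in seq_along(pass)) {
    if (pass[i] && is.na(start)) start <- i
    if ((!pass[i] || i == length(pass)) && !is.na(start)) {
      end <- if (pass[i]) i else i - 1
      if (end - start + 1 >= minlen) runs[[length(runs) + 1]] <- start:end
      start <- NA
    }
  }
  runs
}

# Benjamini-Hochberg step-up, literal definition
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i / m * q) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[1:k]] <- TRUE
  rej
}

# paired t, p and Hedges g from the formulas
oracle_paired <- function(x, y) {
  d <- x - y; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t), n - 1)
  J <- 1 - 3 / (4 * (n - 1) - 1)
  list(t = t, p = p, g = J * mean(d) / sd(d))
}

# synthetic cycle frame: contiguous idealised cycles with controllable
# features, for run-formation and trimming tests
mk_cycles <- function(n, fs = 250, period = 40, amp = 20, start = 1000,
                      band = "4-8") {
  neg <- start + period * (seq_len(n) - 1)
  data.frame(prev_pos = neg - period %/% 2, neg = neg,
             next_pos = neg + period %/% 2,
             rise_amp = amp, decay_amp = amp, amp = amp,
             period_prev = c(NA, rep(period / fs, n - 1)),
             period_next = c(rep(period / fs, n - 1), NA),
             mono_time_rise = 1, mono_time_decay = 1, mono_amp = 1,
             is_local_min = TRUE, band = band)
}

# burst record built from a cycle frame, matching the package's layout
mk_burst <- function(cycles, fs = 250, channel = 1L, polarity = "direct") {
  start <- min(cycles$prev_pos); end <- max(cycles$next_pos)
  negs <- sort(cycles$neg)
  list(channel = channel, band = cycles$band[1], polarity = polarity,
       start = start, end = end, start_s = (start - 1) / fs,
       end_s = (end - 1) / fs, n_cycles = nrow(cycles),
       mean_freq = if (nrow(cycles) >= 2) 1 / mean(diff(negs) / fs) else NA,
       mean_amp = mean(cycles$amp), cycles = cycles, fs_hz = fs)
}

# zero background helper
zero_bg <- function(duration_s, fs = 250, n_channels = 1) {
  structure(list(signal = matrix(0, round(duration_s * fs), n_channels),
                 fs_hz = fs, duration_s = duration_s),
            class = "eeg_sim")
}
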