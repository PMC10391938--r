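th <- criteria_thresholds()
band48 <- band_definition(4, 8)

test_that("ideal cycles pass all seven criteria", {
  cyc <- mk_cycles(6, period = 40)  # 6.25 Hz in the 4-8 band
  crit <- evaluate_criteria(cyc, th, band48)
  inner <- 2:5
  expect_true(all(crit[inner, ]))
  # first/last cycles fail the neighbour-dependent criteria by definition
  expect_false(crit[1, "C"]); expect_false(crit[1, "E"])
  expect_false(crit[6, "C"]); expect_false(crit[6, "E"])
})

test_that("a rise/decay ratio below 0.5 fails criterion D only", {
  cyc <- mk_cycles(5, period = 40)
  cyc$rise_amp[3] <- 0.45 * cyc$decay_amp[3]
  cyc$amp[3] <- (cyc$rise_amp[3] + cyc$decay_amp[3]) / 2
  crit <- evaluate_criteria(cyc, th, band48)
  expect_false(crit[3, "D"])
  expect_true(all(crit[3, c("A", "B", "C", "F", "G")]))
})

test_that("alternating 0.10/0.20 s periods fail criterion C", {
  cyc <- mk_cycles(5, period = 40)
  cyc$period_prev[3] <- 0.10
  cyc$period_next[3] <- 0.20
  crit <- evaluate_criteria(cyc, th, band48)
  expect_false(crit[3, "C"])  # ratio 0.5 < 0.6
  expect_true(crit[3, "B"])   # mean 0.15 still inside 0.125-0.25
})

test_that("criterion thresholds are validated", {
  expect_error(criteria_thresholds(period_ratio = 0), "\\(0, 1\\]")
  expect_error(criteria_thresholds(min_cycles = 1), "at least 2")
})

test_that("bursts are maximal runs of at least four passing cycles", {
  cyc <- mk_cycles(12, period = 40)
  bursts <- detect_bursts(cyc, th, band48, 250)
  expect_length(bursts, 1)
  expect_equal(bursts[[1]]$n_cycles, 10)  # interior cycles of 12
  # three passing cycles between failures never form a burst
  cyc5 <- mk_cycles(5, period = 40)       # 3 interior passing cycles
  expect_length(detect_bursts(cyc5, th, band48, 250), 0)
})

test_that("run formation matches the run-length oracle on random patterns", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    cyc <- mk_cycles(n, period = 40)
    # force failures at random interior positions via criterion G
    fail_at <- sample(2:(n - 1), sample(0:4, 1))
    cyc$mono_amp[fail_at] <- 0.2
    crit <- evaluate_criteria(cyc, th, band48)
    runs <- oracle_runs(attr(crit, "pass"), th$min_cycles)
    bursts <- detect_bursts(cyc, th, band48, 250)
    expect_length(bursts, length(runs))
    if (length(runs))
      expect_equal(vapply(bursts, `[[`, 0, "n_cycles"),
                   vapply(runs, length, 0))
  }
})

test_that("burst records carry frequency and amplitude of their cycles", {
  cyc <- mk_cycles(12, period = 40, amp = 30)
  b <- detect_bursts(cyc, th, band48, 250)[[1]]
  expect_equal(b$mean_freq, 250 / 40)
  expect_equal(b$mean_amp, 30)
  expect_true(b$start < b$end)
})

test_that("dual polarity detects mu-like rhythms on the inverted trace", {
  fs <- 250
  bg <- zero_bg(40, fs)
  # strongly asymmetric cycles: sharp troughs, flat crests
  sim <- insert_bursts(bg, data.frame(channel = 1, freq_hz = 6,
                                      n_cycles = 10, amp_uV = 20,
                                      onset_s = 15), asymmetry = 0.2)
  fit <- detect_eeg_bursts(sim$signal$signal, fs)
  expect_gte(nrow(fit$table), 1)
  # symmetric waveform: both polarities fire, resolution keeps one
  sim2 <- insert_bursts(bg, data.frame(channel = 1, freq_hz = 6,
                                       n_cycles = 10, amp_uV = 20,
                                       onset_s = 15))
  flt <- design_band_filter(band48, fs)
  raw <- sim2$signal$signal[, 1]
  both <- detect_dual_polarity(raw, flt, th)
  expect_gte(length(both), 2)
  resolved <- resolve_within_channel(both)
  expect_length(resolved, 1)
  # zero signal: nothing anywhere
  expect_equal(nrow(detect_eeg_bursts(matrix(0, fs * 20, 1), fs)$table), 0)
})

test_that("within-channel resolution keeps the largest burst intact", {
  b_long <- mk_burst(mk_cycles(10, start = 1000, period = 40))
  b_short <- mk_burst(mk_cycles(5, start = 1040, period = 25, band = "8-12"))
  kept <- resolve_within_channel(list(b_long, b_short))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$n_cycles, 10)
  # disjoint bursts both survive untouched
  b_far <- mk_burst(mk_cycles(5, start = 9000, period = 25, band = "8-12"))
  kept2 <- resolve_within_channel(list(b_long, b_far))
  expect_length(kept2, 2)
  expect_equal(sort(vapply(kept2, `[[`, 0, "n_cycles")), c(5, 10))
})

test_that("trimmed remnants survive only with four or more cycles", {
  # 9-cycle burst; 8-cycle burst overlapping its first 3 cycles
  b9 <- mk_burst(mk_cycles(9, start = 2000, period = 40))
  # competitor ends inside b9's cycle 3; its tail 5 cycles are clear
  b8 <- mk_burst(mk_cycles(8, start = 2000 - 5 * 40, period = 40))
  kept <- resolve_within_channel(list(b9, b8))
  expect_length(kept, 2)
  expect_equal(sort(vapply(kept, `[[`, 0, "n_cycles")), c(5, 9))
  # oracle: cycles of the trimmed burst must all clear the winner's span
  win <- kept[[which.max(vapply(kept, `[[`, 0, "n_cycles"))]]
  rem <- kept[[which.min(vapply(kept, `[[`, 0, "n_cycles"))]]
  expect_true(all(rem$cycles$next_pos <= win$start |
                    rem$cycles$prev_pos >= win$end))
})

test_that("resolved bursts form an antichain under temporal overlap", {
  set.seed(123)
  for (rep in 1:30) {
    bursts <- lapply(1:6, function(i)
      mk_burst(mk_cycles(sample(4:12, 1), start = sample(500:3000, 1),
                         period = sample(c(25, 40, 60), 1))))
    kept <- resolve_within_channel(bursts)
    if (length(kept) >= 2) {
      for (i in 1:(length(kept) - 1)) for (j in (i + 1):length(kept)) {
        a <- kept[[i]]; b <- kept[[j]]
        expect_true(a$end <= b$start || b$end <= a$start)
      }
    }
    # oracle cross-check: every surviving cycle run is >= 4 cycles
    expect_true(all(vapply(kept, `[[`, 0, "n_cycles") >= 4))
  }
})

test_that("detection is invariant to amplitude scaling and DC offsets", {
  fs <- 250
  bg <- gen_aperiodic_eeg(30, fs, exponent = 1, scale_uV = 10,
                          n_channels = 1, seed = 5)
  sim <- insert_bursts(bg, data.frame(channel = 1, freq_hz = 6,
                                      n_cycles = 10, amp_uV = 60,
                                      onset_s = 12))
  x <- sim$signal$signal[, 1]
  base <- detect_eeg_bursts(x, fs)$table
  scaled <- detect_eeg_bursts(7 * x, fs)$table
  offset <- detect_eeg_bursts(x + 100, fs)$table
  expect_equal(scaled[c("start_s", "end_s", "n_cycles")],
               base[c("start_s", "end_s", "n_cycles")])
  expect_equal(scaled$mean_amp_uV, 7 * base$mean_amp_uV, tolerance = 1e-8)
  expect_equal(offset[c("start_s", "end_s", "n_cycles")],
               base[c("start_s", "end_s", "n_cycles")])
})

test_that("noise-free fixtures are recovered with exact cycle counts", {
  fs <- 250
  for (f in c(6, 10)) {
    sim <- insert_bursts(zero_bg(40, fs),
                         data.frame(channel = 1, freq_hz = f,
                                    n_cycles = 9, amp_uV = 20,
                                    onset_s = 15))
    fit <- detect_eeg_bursts(sim$signal$signal, fs)
    expect_equal(nrow(fit$table), 1)
    expect_equal(fit$table$n_cycles, sim$truth$n_cycles)
    expect_equal(fit$table$mean_freq_hz, f, tolerance = 0.05)
    expect_equal(fit$table$mean_amp_uV, 20, tolerance = 0.02)
  }
})

test_that("criteria evaluation matches the brute-force oracle on noise", {
  fs <- 250
  flt <- design_band_filter(band_definition(6, 10), fs)
  set.seed(404)
  for (rep in 1:100) {
    raw <- bandpass_broadband(rnorm(fs * 5, sd = 10), fs)
    cyc <- parse_cycles(raw, flt)
    if (nrow(cyc) == 0) next
    crit <- evaluate_criteria(cyc, th, flt$band)
    orc <- oracle_criteria(cyc, th, band_period_range(flt$band))
    expect_equal(unname(crit == TRUE), unname(orc))
  }
})
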