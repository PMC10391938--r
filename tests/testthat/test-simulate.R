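test_that("aperiodic background has the requested spectral slope", {
  fs <- 250
  for (ex in c(1, 2)) {
    bg <- gen_aperiodic_eeg(100, fs, exponent = ex, scale_uV = 10,
                            n_channels = 1, seed = 42)
    p <- welch_psd(bg$signal[, 1], fs)
    sel <- p$freq_hz >= 1 & p$freq_hz <= 30
    fit <- lm(log10(p$psd[sel]) ~ log10(p$freq_hz[sel]))
    expect_equal(unname(coef(fit)[2]), -ex, tolerance = 0.3)
  }
  # exponent 0: flat spectrum (slope ~ 0)
  bg0 <- gen_aperiodic_eeg(100, fs, exponent = 0, scale_uV = 10,
                           n_channels = 1, seed = 42)
  p0 <- welch_psd(bg0$signal[, 1], fs)
  sel <- p0$freq_hz >= 1 & p0$freq_hz <= 30
  fit0 <- lm(log10(p0$psd[sel]) ~ log10(p0$freq_hz[sel]))
  expect_equal(unname(coef(fit0)[2]), 0, tolerance = 0.1)
})

test_that("background dimensions, scaling and determinism hold", {
  bg <- gen_aperiodic_eeg(10, 250, exponent = 1, scale_uV = 7,
                          n_channels = 3, seed = 1)
  expect_equal(dim(bg$signal), c(2500, 3))
  expect_equal(apply(bg$signal, 2, sd), rep(7, 3), tolerance = 1e-10)
  bg2 <- gen_aperiodic_eeg(10, 250, exponent = 1, scale_uV = 7,
                           n_channels = 3, seed = 1)
  expect_identical(bg$signal, bg2$signal)
  expect_error(gen_aperiodic_eeg(-1, 250), "positive")
  expect_error(gen_aperiodic_eeg(10, 50), "at least 100")
})

test_that("burst insertion validates specs and leaves ground truth faithful", {
  bg <- zero_bg(30)
  # empty spec: identity
  out <- insert_bursts(bg, data.frame())
  expect_identical(out$signal$signal, bg$signal)
  # overlap within a channel rejected
  expect_error(insert_bursts(bg, data.frame(
    channel = 1, freq_hz = 6, n_cycles = c(10, 10), amp_uV = 20,
    onset_s = c(5, 6))), "overlapping")
  # placement outside the recording rejected
  expect_error(insert_bursts(bg, data.frame(
    channel = 1, freq_hz = 6, n_cycles = 10, amp_uV = 20, onset_s = 29)),
    "fit inside")
  # ground truth reports the nominal frequency, amplitude and cycle count
  sim <- insert_bursts(bg, data.frame(channel = 1, freq_hz = 6,
                                      n_cycles = 10, amp_uV = 20,
                                      onset_s = 10))
  expect_equal(sim$truth$band, "theta")
  expect_equal(sim$truth$n_cycles, 10L)
  # the emitted waveform peaks at half the peak-to-peak amplitude
  expect_equal(max(sim$signal$signal), 10, tolerance = 0.01)
  expect_equal(min(sim$signal$signal), -10, tolerance = 0.01)
})

test_that("ground truth is recomputable by scanning the noise-free signal", {
  sim <- insert_bursts(zero_bg(30), data.frame(
    channel = 1, freq_hz = 8, n_cycles = 8, amp_uV = 30, onset_s = 12))
  x <- sim$signal$signal[, 1]
  on <- range(which(x != 0))
  expect_equal((on[1] - 1) / 250, sim$truth$wave_onset_s, tolerance = 0.02)
  expect_equal(diff(on) / 250, sim$truth$wave_dur_s, tolerance = 0.02)
})

test_that("oddball sequences respect counts, ISI and gap invariants", {
  for (seed in 1:50) {
    seq <- gen_oddball_sequence(seed = seed)
    expect_equal(nrow(seq), 200)
    expect_equal(sum(seq$type == "target"), 40)
    isi <- diff(seq$onset_s)
    expect_true(all(isi >= 1.8 & isi <= 2.4))
    tpos <- which(seq$type == "target")
    expect_true(all(diff(tpos) - 1 >= 3))
  }
  # reproducible from the seed
  expect_identical(gen_oddball_sequence(seed = 77),
                   gen_oddball_sequence(seed = 77))
  # degenerate: no targets
  s0 <- gen_oddball_sequence(n_target = 0, seed = 5)
  expect_equal(nrow(s0), 160)
  expect_true(max(s0$onset_s) >= 159 * 1.8 && max(s0$onset_s) <= 159 * 2.4)
  expect_error(gen_oddball_sequence(n_standard = 10, n_target = 40),
               "infeasible")
})

test_that("study simulation follows the configured trajectories", {
  # no dip, no noise: WMZ contrast is zero only if S5..S8 are collinear in
  # time, which the saturating exponential is not; but with dip 0 and huge
  # rate the trajectory is flat at the asymptote
  cfg <- study_config(n_participants = 5, rate = 1e6, wmz_dip = 0,
                      noise_sd = 0, seed = 2)
  sim <- gen_study(cfg)
  amp <- sim$wide$amplitude
  expect_true(all(abs(amp - cfg$asymptote) < 1e-8))
  wc <- wmz_contrast(as.data.frame(amp))
  expect_equal(wc$statistic, rep(0, 5))
  # dip 1, no noise: recovered contrast equals minus the dip exactly
  cfg2 <- study_config(n_participants = 5, rate = 1e6, wmz_dip = 1,
                       noise_sd = 0, seed = 2)
  wc2 <- wmz_contrast(as.data.frame(gen_study(cfg2)$wide$amplitude))
  expect_equal(wc2$statistic, rep(-1, 5))
  # schedule must be ordered
  bad <- session_schedule(); bad["S3"] <- 23
  expect_error(study_config(schedule = bad), "ordered")
})

test_that("study tables are long-format with one value per key", {
  sim <- gen_study(study_config(n_participants = 4, seed = 3))
  tab <- sim$table
  key <- paste(tab$participant, tab$condition, tab$session, tab$outcome)
  expect_equal(anyDuplicated(key), 0)
  expect_equal(nrow(tab), 4 * 8 * 2)
  expect_identical(gen_study(study_config(n_participants = 4, seed = 3))$table,
                   tab)
})

test_that("validation fixtures measure sensitivity and precision", {
  # tiny fixture: 4 bursts, 2 channels; detection matched at >= 50% overlap
  fx <- burst_validation_fixture(seed = 6, n_bursts = 4, n_channels = 2)
  fit <- detect_eeg_bursts(fx$signal$signal, fx$signal$fs_hz)
  m <- match_bursts(fx$events, aggregate_spans(fit, min_channels = 2))
  expect_equal(m$n_truth, 4)
  expect_gte(m$sensitivity, 0.75)
  expect_gte(m$precision, 0.75)
  # match_bursts itself: exact intervals give perfect scores
  ev <- data.frame(onset_s = c(1, 5), dur_s = c(1, 1))
  iv <- data.frame(start_s = c(1, 5), end_s = c(2, 6))
  mm <- match_bursts(ev, iv)
  expect_equal(mm$sensitivity, 1)
  expect_equal(mm$precision, 1)
  expect_equal(match_bursts(ev, iv[0, ])$precision, NA_real_)
})
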