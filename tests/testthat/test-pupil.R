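fs50 <- 50

test_that("closure detection finds below-confidence runs", {
  conf <- rep(0.95, 500)
  conf[101:140] <- 0.2  # 0.8 s closure
  ev <- detect_closures(conf, fs50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 0.8)
  expect_equal(ev$start_s, 2.0)
})

test_that("50 ms hysteresis merges interruptions and drops isolated dips", {
  conf <- rep(0.95, 500)
  conf[101:140] <- 0.2
  conf[121:122] <- 0.9   # 40 ms confident span inside the closure
  ev <- detect_closures(conf, fs50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 0.8)   # merged straight through
  conf2 <- rep(0.95, 500)
  conf2[200] <- 0.1      # isolated 20 ms dip
  expect_equal(nrow(detect_closures(conf2, fs50)), 0)
})

test_that("closure detection ignores diameter and is idempotent", {
  set.seed(5)
  conf <- rep(0.95, 400)
  conf[50:120] <- 0.3
  ev1 <- detect_closures(conf, fs50)
  # re-deriving a confidence series from the detected state reproduces it
  conf_round <- rep(0.95, 400)
  for (i in seq_len(nrow(ev1)))
    conf_round[ev1$start_idx[i]:(ev1$end_idx[i] - 1)] <- 0.1
  expect_equal(detect_closures(conf_round, fs50)[c("start_s", "duration_s")],
               ev1[c("start_s", "duration_s")])
})

test_that("blink/microsleep split at one second", {
  ev <- data.frame(start_s = c(1, 5, 10), duration_s = c(0.3, 0.999, 1.5),
                   start_idx = 1, end_idx = 2)
  cls <- classify_closures(ev, duration_s = 60)
  expect_equal(cls$n_blinks, 2)
  expect_equal(cls$n_microsleeps, 1)
  expect_equal(cls$blink_rate_min, 2)
  expect_equal(cls$microsleep_fraction, 1.5 / 60)
  empty <- classify_closures(ev[0, ], duration_s = 60)
  expect_equal(empty$blink_rate_min, 0)
  expect_equal(empty$microsleep_fraction, 0)
})

test_that("pixel-to-millimetre conversion follows the iris formula", {
  cal <- iris_calibration(iris_cm = 1.2, video_width_px = 192,
                          video_width_cm = 4.5)
  # pupil spanning the iris's own pixel extent maps to the 12 mm standard
  iris_px <- cal$iris_cm / cal$video_width_cm * cal$video_width_px
  expect_equal(px_to_mm(iris_px, cal), 12)
  expect_equal(px_to_mm(20, cal), 20 * 4.5 * 12 / (1.2 * 192))
  expect_equal(px_to_mm(20, cal), 4.6875)
  # doubling pixel width (fixed cm) halves the result; linear in px
  cal2 <- iris_calibration(1.2, video_width_px = 384, video_width_cm = 4.5)
  expect_equal(px_to_mm(20, cal2), px_to_mm(20, cal) / 2)
  expect_equal(px_to_mm(c(10, 20), cal), px_to_mm(10, cal) * c(1, 2))
  expect_error(iris_calibration(0), "positive")
})

test_that("trace cleaning interpolates short gaps then drops short islands", {
  d <- c(rep(2, 50), rep(NA, 15), rep(4, 50))  # 0.3 s gap
  v <- !is.na(d)
  cl <- clean_trace(d, v, fs50)
  expect_true(all(cl$valid))
  expect_equal(cl$diameter[51:65],
               2 + (4 - 2) * (51:65 - 50) / 16)  # straight line
  # 0.4 s island between long gaps is removed
  d2 <- c(rep(NA, 60), rep(3, 20), rep(NA, 60))
  cl2 <- clean_trace(d2, !is.na(d2), fs50)
  expect_true(all(is.na(cl2$diameter)))
  # no gaps: identity
  d3 <- runif(100)
  cl3 <- clean_trace(d3, rep(TRUE, 100), fs50)
  expect_equal(cl3$diameter, d3)
  expect_warning(clean_trace(rep(NA_real_, 10), rep(FALSE, 10), fs50),
                 "entirely invalid")
})

test_that("synthetic pupil traces are recovered exactly at zero noise", {
  g <- gen_pupil_trace(360, fs50, baseline_mm = 4, blink_rate_per_min = 10,
                       microsleep_fraction = 0.1, noise_sd = 0, seed = 21)
  ev <- detect_closures(g$trace$confidence, fs50)
  cls <- classify_closures(ev, 360)
  expect_equal(cls$n_blinks, sum(g$closures$kind == "blink"))
  expect_equal(cls$n_microsleeps, sum(g$closures$kind == "microsleep"))
  expect_equal(sort(ev$start_s), sort(g$closures$start_s))
  # closed-time share near the requested fraction
  expect_equal(sum(g$closures$duration_s[g$closures$kind == "microsleep"]) /
                 360, 0.1, tolerance = 0.02)
  # conversion round-trip: diameters come back in millimetres
  mm <- px_to_mm(g$trace$diameter_px, g$calibration)
  open <- g$trace$confidence >= 0.5
  expect_equal(mm[open], rep(4, sum(open)), tolerance = 1e-10)
})

test_that("blink counts follow the requested Poisson rate", {
  counts <- vapply(1:20, function(s) {
    g <- gen_pupil_trace(360, fs50, blink_rate_per_min = 10,
                         noise_sd = 0, seed = 100 + s)
    sum(g$closures$kind == "blink")
  }, 0)
  expect_equal(mean(counts), 60, tolerance = 0.15)
  g0 <- gen_pupil_trace(60, fs50, blink_rate_per_min = 0, noise_sd = 0,
                        seed = 1)
  expect_equal(nrow(g0$closures), 0)
  expect_equal(var(g0$trace$diameter_px), 0)  # noiseless, eventless
  expect_error(gen_pupil_trace(60, blink_rate_per_min = -1),
               "non-negative")
})

test_that("oddball epochs are baseline-corrected and averaged", {
  fs <- 50
  dur <- 600
  time_s <- (0:(dur * fs - 1)) / fs
  ev <- gen_oddball_sequence(seed = 3)
  ev$onset_s <- ev$onset_s + 10
  # deterministic dilation after every target only
  d <- rep(4, length(time_s))
  for (o in ev$onset_s[ev$type == "target"]) {
    idx <- which(time_s > o & time_s <= o + 2)
    d[idx] <- d[idx] + 1
  }
  s <- oddball_session(time_s, d, ev, fs)
  expect_true(s$usable)
  expect_equal(s$n_target, 40)
  # one standard per target with a preceding standard (a target-first
  # sequence loses that pairing)
  n_paired <- sum(vapply(which(ev$type == "target"), function(i)
    any(ev$type[seq_len(i - 1)] == "standard"), TRUE))
  expect_equal(s$n_standard, n_paired)
  base <- s$rel_time_s >= -0.5 & s$rel_time_s < 0
  expect_equal(mean(s$target[base]), 0, tolerance = 1e-10)
  expect_equal(mean(s$standard[base]), 0, tolerance = 1e-10)
  win <- s$rel_time_s >= 0.5 & s$rel_time_s <= 2
  expect_equal(mean((s$target - s$standard)[win]), 1, tolerance = 0.05)
})

test_that("a constant 1 z-unit difference integrates to 1.5 z s", {
  rel <- seq(-0.5, 2, by = 1 / 50)
  mk <- function(target_minus_standard) {
    list(usable = TRUE, reason = NA, rel_time_s = rel,
         target = rep(target_minus_standard, length(rel)),
         standard = rep(0, length(rel)), n_target = 20, n_standard = 20)
  }
  sessions <- lapply(1:6, function(i) mk(c(2, -2, 3, -3, 4, -4)[i]))
  res <- oddball_response(sessions, min_sessions = 6)
  expect_true(res$usable)
  # z-scoring rescales; the AUC of a constant difference c is c * 1.5
  pool <- unlist(lapply(sessions, function(s) c(s$target, s$standard)))
  expect_equal(res$responses$auc_z_s,
               c(2, -2, 3, -3, 4, -4) / sd(pool) * 1.5, tolerance = 1e-8)
})

test_that("the printed exclusion rules each trigger", {
  fs <- 50
  time_s <- (0:(300 * fs - 1)) / fs
  d <- rep(4, length(time_s))
  # 12 usable target trials only -> session dropped
  ev <- data.frame(onset_s = seq(5, 5 + 11 * 4, by = 4), type = "target")
  ev <- rbind(ev, data.frame(onset_s = ev$onset_s - 2, type = "standard"))
  s <- oddball_session(time_s, d, ev, fs)
  expect_false(s$usable)
  expect_match(s$reason, "fewer than 15")
  # trial with half its samples missing is excluded
  ev2 <- gen_oddball_sequence(n_standard = 80, n_target = 20, seed = 4)
  ev2$onset_s <- ev2$onset_s + 10
  d2 <- rep(4, length(time_s))
  first_target <- ev2$onset_s[ev2$type == "target"][1]
  kill <- which(time_s >= first_target - 0.5 & time_s <= first_target + 2)
  d2[kill[seq_len(ceiling(length(kill) / 2))]] <- NA
  s2 <- oddball_session(time_s, d2, ev2, fs)
  expect_equal(s2$n_target, 19)  # one trial lost to the 2/3 rule
  # participant with under 6 usable sessions is dropped
  bad <- list(usable = FALSE, reason = "x", rel_time_s = 0,
              target = NULL, standard = NULL, n_target = 0, n_standard = 0)
  rel <- seq(-0.5, 2, by = 1 / 50)
  good <- list(usable = TRUE, reason = NA, rel_time_s = rel,
               target = rnorm(length(rel)), standard = rnorm(length(rel)),
               n_target = 20, n_standard = 20)
  res <- oddball_response(c(rep(list(good), 5), rep(list(bad), 7)))
  expect_false(res$usable)
  expect_match(res$reason, "only 5 of 12")
})

test_that("timepoint-level pooling rule drops sparse sessions", {
  fs <- 50
  time_s <- (0:(300 * fs - 1)) / fs
  ev <- gen_oddball_sequence(n_standard = 64, n_target = 16, seed = 6)
  ev$onset_s <- ev$onset_s + 10
  d <- rep(4, length(time_s))
  # knock out one late epoch timepoint in 8 of 16 target trials:
  # those trials stay (>2/3 clean) but the timepoint pools < 10 trials
  tg <- ev$onset_s[ev$type == "target"]
  for (o in tg[1:8]) {
    idx <- which(time_s >= o + 1.9 & time_s <= o + 2)
    d[idx] <- NA
  }
  s <- oddball_session(time_s, d, ev, fs, min_trials = 15)
  expect_false(s$usable)
  expect_match(s$reason, "fewer than 10")
})
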