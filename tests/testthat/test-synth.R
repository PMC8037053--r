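# Protocol schedule, EEG synthesis and gaze generation.

test_that("trial schedule is cross / reading / cross / code with protocol durations", {
  cfg <- cohort_config(n_subjects = 2)
  s <- build_schedule(cfg, 0)
  expect_equal(s$kind, c("cross", "reading", "cross", "code"))
  expect_equal(s$duration, c(30, 60, 30, 600))
  expect_equal(s$label[4], "C1")
  expect_equal(s$label[2], "Control-1")
  # code labels follow trial order C1 -> C2 -> C3
  expect_equal(build_schedule(cfg, 1)$label[4], "C2")
  expect_equal(build_schedule(cfg, 2)$label[4], "C3")
  expect_error(build_schedule(cfg, 3), "out of range")
})

test_that("multi-trial schedules have strictly increasing onsets matching cumulative durations", {
  cfg <- tiny_config()
  one <- cohort_config(n_subjects = 2, n_trials = 1)
  expect_equal(nrow(subject_schedule(one)), 4)
  sched <- do.call(rbind, list(build_schedule(cfg, 0),
                               build_schedule(cfg, 1, t0 = 22)))
  expect_equal(nrow(sched), 8)
  expect_true(all(diff(sched$onset) > 0))
  # brute-force accumulation oracle
  acc <- cumsum(c(0, sched$duration[-8]))
  expect_equal(sched$onset, acc)
  full <- subject_schedule(cfg)
  expect_equal(schedule_duration(full), sum(full$duration))
  expect_equal(full$onset, cumsum(c(0, full$duration[-nrow(full)])))
})

test_that("config validation rejects bad protocols and montages", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(cross_duration = 0), "durations")
  expect_error(cohort_config(channels = c("FZ", "F2", "PZ")), "must include")
  expect_error(cohort_config(channels = c(montage_1010()$label[-60], "XX9")),
               "10-10")
})

test_that("recording synthesis is deterministic and covers the schedule", {
  cfg <- tiny_config(fs = 200, seed = 3)
  sched <- build_schedule(cfg, 0)
  r1 <- generate_recording(sched, cfg, seed = 9)
  r2 <- generate_recording(sched, cfg, seed = 9)
  expect_identical(r1$data, r2$data)
  expect_equal(ncol(r1$data), sum(sched$duration) * cfg$fs)
  r3 <- generate_recording(sched, cfg, seed = 10)
  expect_false(identical(r1$data, r3$data))
})

# independent band-power oracle: mean squared band-passed signal
butter_band_power <- function(x, fs, lo, hi) {
  b <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  mean(signal::filtfilt(b, x)^2)
}

test_that("theta rises and alpha falls with load at target electrodes", {
  cfg <- cohort_config(n_subjects = 2, fs = 200, cross_duration = 2,
                       reading_duration = 30, code_durations = rep(30, 3),
                       load_jitter_sd = 0, seed = 1)
  sched <- build_schedule(cfg, 0)
  rec <- generate_recording(sched, cfg, load = c(0, 0, 0, 2), seed = 4)
  fz <- rec$data["FZ", ]
  lo_idx <- (sched$onset[2] * cfg$fs + 1):(sched$onset[3] * cfg$fs)   # load 0
  hi_idx <- (sched$onset[4] * cfg$fs + 1):ncol(rec$data)              # load 2
  # Welch-style comparison over >= 30 one-second windows per condition
  win_pow <- function(idx, lo, hi) {
    starts <- seq(1, length(idx) - cfg$fs, by = cfg$fs)
    vapply(starts, function(s)
      butter_band_power(fz[idx[s:(s + cfg$fs - 1)]], cfg$fs, lo, hi),
      numeric(1))
  }
  th0 <- win_pow(lo_idx, 4, 8); th2 <- win_pow(hi_idx, 4, 8)
  al0 <- win_pow(lo_idx, 8, 13); al2 <- win_pow(hi_idx, 8, 13)
  expect_gte(length(th0), 29)
  expect_gt(mean(th2), mean(th0))
  expect_lt(mean(al2), mean(al0))
})

test_that("null band effect gives statistically equal theta power across events", {
  cfg <- cohort_config(n_subjects = 2, fs = 200, cross_duration = 2,
                       reading_duration = 20, code_durations = rep(20, 3),
                       band_effect = c(Theta = 0, Alpha = 0),
                       load_jitter_sd = 0, seed = 2)
  sched <- build_schedule(cfg, 0)
  rec <- generate_recording(sched, cfg, load = c(0, 0, 0, 2), seed = 5)
  fz <- rec$data["FZ", ]
  pow <- function(idx) {
    starts <- seq(1, length(idx) - cfg$fs, by = cfg$fs)
    vapply(starts, function(s)
      butter_band_power(fz[idx[s:(s + cfg$fs - 1)]], cfg$fs, 4, 8), numeric(1))
  }
  p0 <- pow((sched$onset[2] * cfg$fs + 1):(sched$onset[3] * cfg$fs))
  p2 <- pow((sched$onset[4] * cfg$fs + 1):ncol(rec$data))
  expect_gt(t.test(p0, p2)$p.value, 0.01)
})

test_that("theta/alpha ratio is monotone in load across seeds", {
  cfg <- cohort_config(n_subjects = 2, fs = 200, cross_duration = 2,
                       reading_duration = 6, code_durations = rep(6, 3),
                       load_jitter_sd = 0, subject_sd = 0, seed = 1)
  sched <- build_schedule(cfg, 0)
  loads <- c(0, 1, 2)
  ratios <- matrix(NA_real_, 20, 3)
  for (sd_i in 1:20) {
    rec <- generate_recording(sched, cfg, load = c(0, loads[1], 0, loads[2]),
                              seed = 100 + sd_i)
    rec2 <- generate_recording(sched, cfg, load = c(0, 0, 0, loads[3]),
                               seed = 100 + sd_i)
    fz <- function(r, ev) {
      idx <- (sched$onset[ev] * cfg$fs + 1):
        ((sched$onset[ev] + sched$duration[ev]) * cfg$fs)
      x <- r$data["FZ", idx]
      butter_band_power(x, cfg$fs, 4, 8) / butter_band_power(x, cfg$fs, 8, 13)
    }
    ratios[sd_i, ] <- c(fz(rec, 2), fz(rec, 4), fz(rec2, 4))
  }
  m <- colMeans(ratios)
  expect_true(all(diff(m) > 0))
})

test_that("gaze is emitted only in code events, biased dwell concentrates on critical AOIs", {
  cfg <- tiny_config(seed = 6)
  sched <- subject_schedule(cfg)
  aois <- generate_aois(cfg)
  gz <- generate_gaze(sched, aois, dwell_bias = 1, seed = 6,
                      screen = cfg$screen)
  code_iv <- sched[sched$kind == "code", ]
  in_code <- vapply(gz$t, function(t)
    any(t >= code_iv$onset & t < code_iv$onset + code_iv$duration), logical(1))
  expect_true(all(in_code))
  expect_true(all(diff(gz$t) > 0))
  # one critical AOI covering 10% of the screen height, bias 5:
  # sampler targets 5*0.1/(5*0.1 + 0.9) ~ 36% > 30%
  a1 <- data.frame(name = "crit", y_min = 0, y_max = 108, critical = TRUE,
                   n_annotators = 4L)
  class(a1) <- c("aoi_set", "data.frame")
  g5 <- generate_gaze(sched, a1, dwell_bias = 5, seed = 7,
                      screen = c(1920, 1080))
  frac <- mean(g5$y >= 0 & g5$y < 108)
  expect_gt(frac, 0.30)
  # unbiased dwell is proportional to area
  g1 <- generate_gaze(sched, a1, dwell_bias = 1, seed = 7,
                      screen = c(1920, 1080))
  expect_lt(abs(mean(g1$y >= 0 & g1$y < 108) - 0.1), 0.08)
  expect_error(generate_gaze(sched, a1[0, ], 1, 1), "empty")
  expect_error(generate_gaze(sched, a1, 0.5, 1), "dwell_bias")
  no_code <- sched[sched$kind != "code", ]
  expect_equal(nrow(generate_gaze(no_code, a1, 1, 1)), 0)
})

test_that("subject simulation is deterministic and TLX respects the 1-6 scale", {
  cfg <- tiny_config(seed = 8)
  s1 <- simulate_subject(cfg, 1)
  s2 <- simulate_subject(cfg, 1)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$gaze, s2$gaze)
  expect_identical(s1$tlx, s2$tlx)
  expect_true(all(s1$tlx$score >= 1 & s1$tlx$score <= 6))
  expect_equal(s1$tlx$task, c("C1", "C2", "C3"))
  expect_true(s1$expertise %in% c("intermediate", "advanced", "expert"))
  s3 <- simulate_subject(cfg, 2)
  expect_false(identical(s1$recording$data, s3$recording$data))
})

test_that("harder code tasks draw NASA-TLX scores from a common saturated distribution", {
  cfg <- tiny_config(n_subjects = 12, seed = 9)
  scores <- do.call(rbind, lapply(1:12, function(s) simulate_subject(cfg, s)$tlx))
  m <- tapply(scores$score, scores$task, mean)
  expect_gt(m[["C2"]], m[["C1"]])
  expect_lt(abs(m[["C2"]] - m[["C3"]]), 1)
})
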