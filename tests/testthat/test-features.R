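# Window enumeration, time/frequency-domain features and the
# feature-count identities.

test_that("window counts follow floor((D - length)/hop) + 1", {
  rec <- new_recording(matrix(0, 1, 60 * 250), 250, "FZ")
  ev <- list(onset = 0, duration = 60, label = "x", kind = "code")
  w <- sliding_windows(rec, window_spec(), ev)
  expect_equal(nrow(w), 296)
  # brute-force enumeration oracle (in samples)
  L <- 250; hop <- 50
  brute <- 0; s <- 1
  while (s + L - 1 <= 60 * 250) { brute <- brute + 1; s <- s + hop }
  expect_equal(nrow(w), brute)
  expect_true(all(w$end <= 60 * 250))
  expect_equal(nrow(sliding_windows(rec, window_spec(),
                                    list(onset = 3, duration = 1))), 1)
  expect_equal(nrow(sliding_windows(rec, window_spec(overlap = 0),
                                    list(onset = 0, duration = 10))), 10)
  expect_error(sliding_windows(rec, window_spec(),
                               list(onset = 0, duration = 0.5, label = "s")),
               "shorter")
})

test_that("Hjorth parameters of a sinusoid match the analytic derivative", {
  fs <- 1000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  td <- time_domain_features(sin(2 * pi * 10 * t), fs)
  expect_equal(unname(td[1, "hjorth_mobility"]), 2 * pi * 10, tolerance = 0.01)
  expect_equal(unname(td[1, "hjorth_complexity"]), 1, tolerance = 0.01)
  expect_equal(unname(td[1, "hjorth_activity"]), unname(td[1, "variance"]))
})

test_that("moment features use the documented conventions", {
  x <- with_seed_test(31, rnorm(1000))
  td <- time_domain_features(x, 1000)
  # biased moment oracles
  m2 <- mean((x - mean(x))^2)
  expect_equal(unname(td[1, "variance"]), m2)
  expect_equal(unname(td[1, "skewness"]), mean((x - mean(x))^3) / m2^1.5)
  expect_equal(unname(td[1, "kurtosis"]), mean((x - mean(x))^4) / m2^2)  # raw, ~3
  expect_lt(abs(td[1, "skewness"]), 0.3)
  expect_lt(abs(td[1, "kurtosis"] - 3), 0.6)
  expect_equal(unname(td[1, "mean_norm"]),
               (mean(x) - min(x)) / (max(x) - min(x)))
  # constant signal: guarded values, mean preserved
  tdc <- time_domain_features(rep(7, 100), 1000)
  expect_equal(unname(tdc[1, "mean_raw"]), 7)
  expect_equal(unname(tdc[1, "variance"]), 0)
  expect_equal(unname(tdc[1, "skewness"]), 0)
  expect_equal(unname(tdc[1, "hjorth_mobility"]), 0)
  expect_true(attr(tdc, "flags")[1])
})

test_that("the periodogram satisfies Parseval and localizes spectral lines", {
  fs <- 250
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  sp <- psd(sin(2 * pi * 10 * t), fs)
  expect_equal(sp$freq[which.max(sp$power[, 1])], 10)
  for (seed in 1:5) {
    x <- with_seed_test(seed, rnorm(fs, sd = runif(1, 0.5, 3)))
    sp <- psd(x, fs)
    v <- mean((x - mean(x))^2)
    expect_equal(sum(sp$power[sp$freq > 0, 1]), v, tolerance = 1e-6)
  }
})

test_that("band powers partition the spectrum; flat spectra give band-width areas", {
  # flat PSD of height c: band area = width * c
  bp <- band_powers(flat_spectrum(c = 2))
  expect_equal(unname(bp$absolute["Theta", 1]), 8)    # 4 bins x 2
  expect_equal(unname(bp$absolute["Alpha", 1]), 10)   # 5 bins
  expect_equal(unname(bp$absolute["Beta", 1]), 34)    # 17 bins
  expect_equal(unname(bp$total[1]), 180)              # 90 bins x 2
  # relative powers always sum to 1
  for (seed in 1:5) {
    x <- with_seed_test(seed + 40, rnorm(250))
    bp <- band_powers(psd(x, 250))
    expect_equal(sum(bp$relative[, 1]), 1, tolerance = 1e-9)
  }
  # 10 Hz line: everything in alpha
  t <- seq(0, 1 - 1 / 250, by = 1 / 250)
  bpa <- band_powers(psd(sin(2 * pi * 10 * t), 250))
  expect_gt(bpa$relative["Alpha", 1], 0.99)
  expect_error(band_powers(psd(rnorm(100), 100)), "below highest band")
})

test_that("band ratios, engagement indexes and brainbeat follow the closed forms", {
  bp <- band_powers(flat_spectrum(c = 1, channels = 2))
  r <- band_ratios(bp)
  expect_equal(nrow(r), choose(7, 2))
  expect_equal(unname(r["Theta_Alpha", 1]), 4 / 5)
  ei <- engagement_indexes(bp)
  expect_equal(unname(ei["index1", 1]), 17 / 9)
  expect_equal(unname(ei["index2", 1]), 4 / 22)
  colnames(bp$absolute) <- c("FZ", "PZ")
  bp$total <- setNames(bp$total, c("FZ", "PZ"))
  expect_equal(brainbeat(bp), 4 / 5)
  # equal power in every band -> all ratios 1, indexes 0.5
  bpe <- bp
  bpe$absolute[] <- 3
  expect_true(all(abs(band_ratios(bpe) - 1) < 1e-12))
  ee <- engagement_indexes(bpe)
  expect_equal(unname(ee["index1", 1]), 0.5)
  expect_equal(unname(ee["index2", 1]), 0.5)
  # theta-dominant limit
  t <- seq(0, 1 - 1 / 250, by = 1 / 250)
  bth <- band_powers(psd(sin(2 * pi * 6 * t), 250))
  eth <- engagement_indexes(bth)
  expect_lt(eth["index1", 1], 0.01)
  expect_gt(eth["index2", 1], 50)
  # theta(Fz) = alpha(Pz) -> brainbeat 1; zero theta -> 0
  bp1 <- bp
  bp1$absolute["Theta", "FZ"] <- bp1$absolute["Alpha", "PZ"]
  expect_equal(brainbeat(bp1), 1)
  bp0 <- bp
  bp0$absolute["Theta", "FZ"] <- 0
  expect_equal(brainbeat(bp0), 0)
})

test_that("spectral summaries find centroids and alpha peaks with the stated tie-break", {
  fs <- 250
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  ss <- spectral_summaries(psd(sin(2 * pi * 10 * t), fs))
  expect_equal(unname(ss["alphapeak", 1]), 10)
  expect_equal(unname(ss["avgfreq", 1]), 10, tolerance = 0.1)
  two <- psd(sin(2 * pi * 20 * t) + sin(2 * pi * 40 * t), fs)
  expect_equal(unname(spectral_summaries(two)["avgfreq", 1]), 30,
               tolerance = 0.1)
  # flat spectrum: tie broken toward the lowest alpha bin
  expect_equal(unname(spectral_summaries(flat_spectrum())["alphapeak", 1]), 8)
})

test_that("asymmetry features cover 9 pairs x 7 bands x 2 with symmetric null", {
  labs <- unique(c(asymmetry_pairs_default()$left,
                   asymmetry_pairs_default()$right, "FZ", "PZ"))
  X <- matrix(rep(with_seed_test(51, rnorm(250)), length(labs)),
              length(labs), byrow = TRUE)
  sp <- psd(X, 250)
  colnames(sp$power) <- labs
  bp <- band_powers(sp)
  colnames(bp$absolute) <- labs
  a <- asymmetry_features(bp)
  expect_length(a, 126)
  expect_true(all(abs(a[grep("dasym", names(a))]) < 1e-12))
  expect_true(all(abs(a[grep("rasym", names(a))] - 1) < 1e-9))
  # doubled left alpha
  bp2 <- bp
  bp2$absolute["Alpha", "F3"] <- 2 * bp2$absolute["Alpha", "F4"]
  a2 <- asymmetry_features(bp2)
  expect_equal(unname(a2["F3_F4__rasym__Alpha"]), 2, tolerance = 1e-9)
  expect_equal(unname(a2["F3_F4__dasym__Alpha"]),
               unname(bp$absolute["Alpha", "F4"]), tolerance = 1e-9)
  bp3 <- bp
  colnames(bp3$absolute) <- sub("^O1$", "XX", colnames(bp3$absolute))
  expect_error(asymmetry_features(bp3), "O1")
})

test_that("the full extraction yields the 480 + 2400 + 127 = 3007 column identity", {
  cfg <- tiny_config(fs = 250, seed = 61)
  sched <- build_schedule(cfg, 0)
  rec <- generate_recording(sched, cfg, seed = 61)
  fm <- extract_all(rec, window_spec(), sched)
  expect_equal(ncol(fm$values), 3007)
  nm <- colnames(fm$values)
  td_cols <- grep("__(mean_raw|mean_norm|variance|skewness|kurtosis|hjorth_activity|hjorth_mobility|hjorth_complexity)$", nm)
  expect_length(td_cols, 480)
  multi_cols <- grep("(dasym|rasym|brainbeat)", nm)
  expect_length(multi_cols, 127)
  expect_length(nm, length(unique(nm)))
  expect_false(anyNA(fm$values))
  # 40 frequency features per channel by name accounting
  fz_freq <- setdiff(grep("^FZ__", nm, value = TRUE),
                     grep("^FZ__", nm[td_cols], value = TRUE))
  expect_length(fz_freq, 40)
  # rows: one block of windows per event
  expect_equal(nrow(fm$values),
               sum(vapply(seq_len(nrow(sched)), function(e)
                 (round(sched$duration[e] * 250) - 250) %/% 50 + 1,
                 numeric(1))))
})

test_that("theta/alpha features increase with the generator's load", {
  cfg <- cohort_config(n_subjects = 2, fs = 200, cross_duration = 2,
                       reading_duration = 5, code_durations = rep(5, 3),
                       load_jitter_sd = 0, subject_sd = 0, seed = 71)
  sched <- build_schedule(cfg, 0)
  rhos <- vapply(1:20, function(s) {
    rec <- generate_recording(sched, cfg, load = c(0, 0.5, 0, 2.5), seed = 200 + s)
    fm <- extract_all(rec, window_spec(), sched, kinds = c("reading", "code"))
    v <- fm$values[, "FZ__ratio__Theta_Alpha"]
    stats::cor(v, sched$load[fm$meta$event], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0)
  expect_gt(mean(rhos > 0), 0.9)
})
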