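#' Cohort configuration for the synthetic study generator
#'
#' Defines the protocol structure and signal model of a synthetic
#' code-comprehension study: each subject performs `n_trials` trials, each
#' consisting of a fixation cross, a natural-language reading control task,
#' a second fixation cross, and a code-comprehension task of increasing
#' nominal complexity (C1, C2, C3). EEG is synthesized as pink noise plus
#' independent band-limited Gaussian noise per canonical band, with theta
#' amplitude scaled up and alpha amplitude scaled down with the task's
#' cognitive-load level, strongest over fronto-parietal midline electrodes.
#'
#' @param n_subjects Number of subjects (default 26).
#' @param n_trials Trials per subject (default 3).
#' @param fs Sampling frequency in Hz (default 1000).
#' @param channels Channel labels; default the 60-channel 10-10 montage.
#' @param cross_duration Fixation-cross duration in seconds (default 30).
#' @param reading_duration Reading control task duration in seconds
#'   (default 60, the protocol maximum).
#' @param code_durations Code-task durations in seconds, one per trial
#'   (default 600 each, the protocol maximum).
#' @param code_loads Cognitive-load scalars per code task. The default
#'   `c(1, 2.3, 2.3)` encodes the mental-effort saturation between the two
#'   harder tasks: their loads are drawn from the same distribution.
#' @param control_load Load scalar of the reading control task.
#' @param band_effect Named numeric: per-band multiplicative amplitude
#'   modulation per unit load (amplitude factor `1 + effect * load * w(ch)`,
#'   floored at 0.1). Default theta +0.35, alpha -0.20, others 0.
#' @param target_channels Channels receiving full load modulation (weight 1).
#' @param off_target_weight Modulation weight of all other channels.
#' @param band_amps Named per-band RMS amplitudes in microvolts.
#' @param noise_floor RMS of the pink-noise floor in microvolts.
#' @param subject_sd Log-normal SD of the per-subject global gain.
#' @param load_jitter_sd SD of the per-event jitter added to load scalars.
#' @param critical_boost Extra load added to theta modulation while the
#'   subject's gaze dwells in a critical AOI (space-time coupling used by
#'   the fusion analysis); 0 disables.
#' @param line_amp Amplitude (microvolts) of an optional 50 Hz powerline
#'   artifact added to all channels; 0 (default) disables.
#' @param blink_rate Rate (per second) of optional blink-like frontal
#'   transients; 0 (default) disables.
#' @param gaze_rate Eye-tracker sampling rate in Hz.
#' @param dwell_bias Multiplicative preference of gaze dwell for critical
#'   AOIs (1 = dwell proportional to area).
#' @param screen Screen size in pixels, c(width, height).
#' @param n_code_lines,line_height,critical_lines Layout of the synthetic
#'   code AOIs: number of code lines, line height in pixels, and indices of
#'   lines marked critical by all annotators.
#' @param seed Integer seed for all generator randomness.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 26, n_trials = 3, fs = 1000,
                          channels = montage_1010()$label,
                          cross_duration = 30, reading_duration = 60,
                          code_durations = rep(600, n_trials),
                          code_loads = c(1, 2.3, 2.3)[seq_len(n_trials)],
                          control_load = 0.25,
                          band_effect = c(Theta = 0.35, Alpha = -0.20),
                          target_channels = c("FZ", "F2", "FCZ", "PZ", "CPZ", "CP2"),
                          off_target_weight = 0.2,
                          band_amps = c(Delta = 8, Theta = 6, Alpha = 10, Beta = 4,
                                        LowGamma = 1.5, MediumGamma = 1.0,
                                        HighGamma = 0.8),
                          noise_floor = 5,
                          subject_sd = 0.15, load_jitter_sd = 0.08,
                          critical_boost = 0,
                          line_amp = 0, blink_rate = 0,
                          gaze_rate = 60, dwell_bias = 3,
                          screen = c(1920, 1080),
                          n_code_lines = 30, line_height = 28,
                          critical_lines = c(8, 9, 17, 18, 19),
                          seed = 1L) {
  channels <- toupper(channels)
  if (n_subjects < 2) stop_cogload("n_subjects must be >= 2")
  if (n_trials < 1) stop_cogload("n_trials must be >= 1")
  if (any(c(cross_duration, reading_duration, code_durations) <= 0))
    stop_cogload("all durations must be > 0")
  if (length(code_durations) != n_trials)
    stop_cogload("code_durations must have one entry per trial")
  if (anyDuplicated(channels)) stop_cogload("channel labels must be unique")
  required <- c("FZ", "F2", "FCZ", "PZ", "CPZ", "CP2")
  miss <- setdiff(required, channels)
  if (length(miss))
    stop_cogload("montage must include %s", paste(miss, collapse = ", "))
  known <- montage_1010()$label
  bad <- setdiff(channels, known)
  if (length(bad))
    stop_cogload("labels not in the 10-10 set: %s", paste(bad, collapse = ", "))
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' Build the event schedule of one trial
#'
#' One trial is the fixed sequence cross, reading control, cross, code
#' comprehension; trials are ordered C1, C2, C3 by increasing nominal
#' complexity.
#'
#' @param config A [cohort_config()].
#' @param trial_index Zero-based trial index (< `n_trials`).
#' @param t0 Onset of the trial in seconds (used when concatenating trials).
#' @return A data.frame of class `event_schedule` with columns
#'   `onset`, `duration`, `kind`, `label`, `trial`, `load`.
#' @export
build_schedule <- function(config, trial_index, t0 = 0) {
  stopifnot(inherits(config, "cohort_config"))
  if (trial_index < 0 || trial_index >= config$n_trials)
    stop_cogload("trial_index %d out of range [0, %d)", trial_index, config$n_trials)
  tr <- trial_index + 1L
  durs <- c(config$cross_duration, config$reading_duration,
            config$cross_duration, config$code_durations[tr])
  if (any(durs <= 0)) stop_cogload("invalid durations in config")
  kinds <- c("cross", "reading", "cross", "code")
  labels <- c("", sprintf("Control-%d", tr), "", sprintf("C%d", tr))
  loads <- c(0, config$control_load, 0, config$code_loads[tr])
  sched <- data.frame(
    onset = t0 + cumsum(c(0, durs[-length(durs)])),
    duration = durs, kind = kinds, label = labels,
    trial = tr, load = loads, stringsAsFactors = FALSE)
  class(sched) <- c("event_schedule", "data.frame")
  sched
}

#' Build the full per-subject schedule (all trials, concatenated)
#'
#' @param config A [cohort_config()].
#' @return An `event_schedule` covering all trials back to back.
#' @export
subject_schedule <- function(config) {
  t0 <- 0
  out <- vector("list", config$n_trials)
  for (i in seq_len(config$n_trials) - 1L) {
    s <- build_schedule(config, i, t0)
    t0 <- s$onset[nrow(s)] + s$duration[nrow(s)]
    out[[i + 1L]] <- s
  }
  sched <- do.call(rbind, out)
  class(sched) <- c("event_schedule", "data.frame")
  sched
}

schedule_duration <- function(schedule) sum(schedule$duration)

# --- signal synthesis -------------------------------------------------------

# Band-limited unit-RMS Gaussian noise, n samples x k channels, via FFT
# masking of white noise to [low, high) Hz.
band_noise <- function(n, k, fs, low, high) {
  w <- matrix(stats::rnorm(n * k), n, k)
  W <- stats::mvfft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  keep <- f >= low & f < high
  W[!keep, ] <- 0
  x <- Re(stats::mvfft(W, inverse = TRUE)) / n
  rms <- sqrt(colMeans(x^2))
  rms[rms == 0] <- 1
  sweep(x, 2, rms, "/")
}

# Pink (1/f) noise, unit RMS per column.
pink_noise <- function(n, k, fs) {
  w <- matrix(stats::rnorm(n * k), n, k)
  W <- stats::mvfft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  g <- ifelse(f > 0, 1 / sqrt(pmax(f, 1e-6)), 0)
  x <- Re(stats::mvfft(W * g, inverse = TRUE)) / n
  rms <- sqrt(colMeans(x^2))
  rms[rms == 0] <- 1
  sweep(x, 2, rms, "/")
}

#' Synthesize a multichannel EEG recording for a schedule
#'
#' Each channel is pink noise plus independent band-limited Gaussian noise
#' per canonical band. The theta-band amplitude scales up and the alpha-band
#' amplitude scales down with the event's load scalar; fronto-parietal
#' midline channels receive the largest modulation. The spectral-feature
#' pipeline consumes only band powers, so no event-related waveform
#' morphology is simulated.
#'
#' @param schedule An `event_schedule` (events contiguous from 0 s).
#' @param config A [cohort_config()].
#' @param load Optional per-event load override (defaults to
#'   `schedule$load`).
#' @param seed Integer seed; identical (schedule, config, load, seed) give
#'   bit-identical output.
#' @param boosts Optional data.frame (`start`, `end`, `amount`, seconds on
#'   the recording timeline) of intervals with extra theta load, used to
#'   couple EEG load to critical-AOI gaze dwell.
#' @param subject_gain Global amplitude factor (per-subject variability).
#' @return An [new_recording()] covering `sum(schedule$duration)` seconds.
#' @export
generate_recording <- function(schedule, config, load = NULL, seed = 1L,
                               boosts = NULL, subject_gain = 1) {
  stopifnot(inherits(config, "cohort_config"))
  load <- load %||% schedule$load
  if (length(load) != nrow(schedule))
    stop_cogload("need one load scalar per event")
  chans <- config$channels
  k <- length(chans)
  fs <- config$fs
  w_ch <- ifelse(chans %in% toupper(config$target_channels), 1,
                 config$off_target_weight)
  bands <- eeg_bands()
  amps <- config$band_amps
  eff <- config$band_effect
  total_n <- as.integer(round(schedule_duration(schedule) * fs))
  X <- matrix(0, k, total_n)
  with_seed(seed, {
    for (ev in seq_len(nrow(schedule))) {
      n <- as.integer(round(schedule$duration[ev] * fs))
      i0 <- as.integer(round(schedule$onset[ev] * fs)) + 1L
      idx <- i0:(i0 + n - 1L)
      ld <- load[ev] + if (config$load_jitter_sd > 0)
        stats::rnorm(1, 0, config$load_jitter_sd) else 0
      ld <- max(ld, 0)
      seg <- t(pink_noise(n, k, fs)) * config$noise_floor
      tsec <- schedule$onset[ev] + (seq_len(n) - 1) / fs
      for (b in seq_len(nrow(bands))) {
        bname <- bands$name[b]
        comp <- t(band_noise(n, k, fs, bands$low[b], bands$high[b]))
        e <- if (bname %in% names(eff)) eff[[bname]] else 0
        if (e != 0) {
          env_load <- rep(ld, n)
          if (bname == "Theta" && !is.null(boosts) && nrow(boosts)) {
            for (r in seq_len(nrow(boosts))) {
              inb <- tsec >= boosts$start[r] & tsec < boosts$end[r]
              env_load[inb] <- env_load[inb] + boosts$amount[r]
            }
          }
          # per-channel, per-sample amplitude factor
          fac <- 1 + outer(w_ch * e, env_load)
          fac[fac < 0.1] <- 0.1
          comp <- comp * fac
        }
        seg <- seg + comp * amps[[bname]]
      }
      if (config$line_amp > 0)
        seg <- seg + config$line_amp *
          matrix(sin(2 * pi * 50 * tsec), k, n, byrow = TRUE)
      if (config$blink_rate > 0) {
        frontal <- chans %in% c("FP1", "FPZ", "FP2", "AF3", "AF4")
        n_blinks <- stats::rpois(1, config$blink_rate * n / fs)
        if (n_blinks > 0 && any(frontal)) {
          bl_t <- sort(stats::runif(n_blinks, 0, n / fs - 0.4))
          shape_n <- as.integer(0.3 * fs)
          shape <- 100 * sin(pi * seq_len(shape_n) / shape_n)^2
          for (bt in bl_t) {
            j0 <- as.integer(bt * fs) + 1L
            jj <- j0:(j0 + shape_n - 1L)
            seg[frontal, jj] <- seg[frontal, jj] +
              matrix(shape, sum(frontal), shape_n, byrow = TRUE)
          }
        }
      }
      X[, idx] <- seg * subject_gain
    }
  })
  new_recording(X, fs, chans, history = sprintf("synthesized(seed=%d)", seed))
}

# --- gaze and AOIs ----------------------------------------------------------

#' Generate the AOI set of the synthetic code screen
#'
#' Code lines are stacked rectangular regions; the configured critical lines
#' are marked critical by all four synthetic annotators (they are the
#' "common critical areas").
#'
#' @param config A [cohort_config()].
#' @param top Pixel offset of the first code line.
#' @return A data.frame of class `aoi_set`: `name`, `y_min`, `y_max`,
#'   `critical`, `n_annotators`.
#' @export
generate_aois <- function(config, top = 100) {
  n <- config$n_code_lines
  h <- config$line_height
  aois <- data.frame(
    name = sprintf("line%02d", seq_len(n)),
    y_min = top + (seq_len(n) - 1) * h,
    y_max = top + seq_len(n) * h,
    critical = seq_len(n) %in% config$critical_lines,
    n_annotators = ifelse(seq_len(n) %in% config$critical_lines, 4L, 0L),
    stringsAsFactors = FALSE)
  class(aois) <- c("aoi_set", "data.frame")
  aois
}

#' Generate a gaze stream for the code events of a schedule
#'
#' Gaze points are emitted only during code-comprehension events, as a
#' sequence of dwells: a screen region (an AOI line or background) is chosen
#' with probability proportional to its area, critical AOIs weighted by
#' `dwell_bias`, and points are emitted at the tracker rate with small
#' jitter for an exponentially distributed dwell duration. Y-coordinates
#' therefore form temporally contiguous clusters.
#'
#' @param schedule An `event_schedule`.
#' @param aois An `aoi_set` (non-empty).
#' @param dwell_bias Critical-AOI preference (>= 1; 1 = area-proportional).
#' @param seed Integer seed.
#' @param rate Tracker sampling rate in Hz.
#' @param screen Screen size c(width, height) in pixels.
#' @param mean_dwell Mean dwell duration in seconds.
#' @return A data.frame of class `gaze_stream`: `t`, `x`, `y`, `valid`.
#' @export
generate_gaze <- function(schedule, aois, dwell_bias = 1, seed = 1L,
                          rate = 60, screen = c(1920, 1080),
                          mean_dwell = 0.7) {
  if (is.null(aois) || nrow(aois) == 0) stop_cogload("AOI set is empty")
  if (dwell_bias < 1) stop_cogload("dwell_bias must be >= 1")
  code_ev <- schedule[schedule$kind == "code", , drop = FALSE]
  heights <- aois$y_max - aois$y_min
  y_span <- screen[2]
  bg <- max(0, y_span - sum(heights))
  wts <- c(heights * ifelse(aois$critical, dwell_bias, 1), bg)
  pts <- list()
  with_seed(seed, {
    for (ev in seq_len(nrow(code_ev))) {
      t <- code_ev$onset[ev]
      t_end <- t + code_ev$duration[ev]
      x <- screen[1] / 2
      while (t < t_end - 1e-9) {
        reg <- sample.int(length(wts), 1, prob = wts)
        dur <- min(stats::rexp(1, 1 / mean_dwell) + 1 / rate, t_end - t)
        tt <- seq(t, t + dur - 1e-9, by = 1 / rate)
        if (length(tt)) {
          if (reg <= nrow(aois)) {
            yc <- stats::runif(1, aois$y_min[reg], aois$y_max[reg])
          } else {
            yc <- stats::runif(1, 0, y_span)  # background
          }
          xs <- pmin(pmax(x + cumsum(stats::rnorm(length(tt), 0, 15)), 50),
                     screen[1] - 50)
          x <- xs[length(xs)]
          pts[[length(pts) + 1L]] <- data.frame(
            t = tt, x = xs,
            y = pmin(pmax(yc + stats::rnorm(length(tt), 0, 4), 0), y_span),
            valid = TRUE)
        }
        t <- t + dur
      }
    }
  })
  gz <- if (length(pts)) do.call(rbind, pts) else
    data.frame(t = numeric(), x = numeric(), y = numeric(), valid = logical())
  gz <- gz[order(gz$t), , drop = FALSE]
  # enforce strictly increasing timestamps
  gz <- gz[!duplicated(gz$t), , drop = FALSE]
  rownames(gz) <- NULL
  class(gz) <- c("gaze_stream", "data.frame")
  gz
}

# Contiguous intervals during which gaze dwells inside critical AOIs.
gaze_critical_intervals <- function(gaze, aois, max_gap = 0.1) {
  if (nrow(gaze) == 0) return(data.frame(start = numeric(), end = numeric()))
  lab <- map_gaze_to_aoi(gaze, aois)
  crit <- !is.na(lab) & aois$critical[match(lab, aois$name)]
  if (!any(crit)) return(data.frame(start = numeric(), end = numeric()))
  tc <- gaze$t[crit]
  brk <- c(TRUE, diff(tc) > max_gap)
  grp <- cumsum(brk)
  data.frame(start = tapply(tc, grp, min), end = tapply(tc, grp, max) + 1e-3)
}

#' Simulate one subject of the synthetic study
#'
#' Builds the full trial schedule, the AOI set, a gaze stream for the code
#' tasks, the EEG recording (with theta load boosted during critical-AOI
#' dwell when `critical_boost > 0`), and NASA-TLX mental-effort scores
#' (load level plus bounded noise, clipped to 1-6; the two harder code
#' tasks draw from the same distribution).
#'
#' @param config A [cohort_config()].
#' @param subject Subject index (integer, used to derive seeds).
#' @param seed Base seed; default the config seed.
#' @return A list of class `subject_data`: `subject`, `recording`,
#'   `schedule`, `gaze`, `aois`, `tlx` (data.frame task/score), `expertise`.
#' @export
simulate_subject <- function(config, subject = 1L, seed = config$seed) {
  sched <- subject_schedule(config)
  aois <- generate_aois(config)
  gz <- generate_gaze(sched, aois, dwell_bias = config$dwell_bias,
                      seed = derive_seed(seed, subject, 1),
                      rate = config$gaze_rate, screen = config$screen)
  boosts <- NULL
  if (config$critical_boost > 0) {
    iv <- gaze_critical_intervals(gz, aois)
    if (nrow(iv)) boosts <- data.frame(start = iv$start, end = iv$end,
                                       amount = config$critical_boost)
  }
  gain <- with_seed(derive_seed(seed, subject, 2),
                    exp(stats::rnorm(1, 0, config$subject_sd)))
  rec <- generate_recording(sched, config, seed = derive_seed(seed, subject, 3),
                            boosts = boosts, subject_gain = gain)
  code_lab <- sched$label[sched$kind == "code"]
  tlx_load <- config$code_loads
  if (config$n_trials >= 3) tlx_load[2:3] <- mean(config$code_loads[2:3])
  tlx <- with_seed(derive_seed(seed, subject, 4), {
    sc <- 1 + 1.8 * tlx_load + stats::rnorm(length(tlx_load), 0, 0.45)
    data.frame(task = code_lab, score = pmin(pmax(sc, 1), 6))
  })
  expertise <- c("intermediate", "advanced", "expert")[1 + subject %% 3]
  structure(list(subject = subject, recording = rec, schedule = sched,
                 gaze = gz, aois = aois, tlx = tlx, expertise = expertise),
            class = "subject_data")
}

#' Simulate a full synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` of [simulate_subject()] results.
#' @export
simulate_cohort <- function(config) {
  out <- lapply(seq_len(config$n_subjects),
                function(s) simulate_subject(config, s))
  class(out) <- "cohort"
  out
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf("<subject_data> subject %d (%s), %d events, %d gaze points\n",
              x$subject, x$expertise, nrow(x$schedule), nrow(x$gaze)))
  invisible(x)
}
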