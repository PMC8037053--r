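# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs quickly.

# a reduced-duration study configuration (protocol structure intact)
tiny_config <- function(n_subjects = 2, fs = 200, seed = 1, ...) {
  cohort_config(n_subjects = n_subjects, fs = fs,
                cross_duration = 4, reading_duration = 6,
                code_durations = c(8, 8, 8), seed = seed, ...)
}

# a small recording with labelled channels (white noise by default)
noise_recording <- function(channels = c("FZ", "F2", "PZ", "CPZ", "CP2",
                                         "FCZ", "C3", "C4"),
                            fs = 250, secs = 4, sd = 1, seed = 1) {
  n <- fs * secs
  X <- with_seed_test(seed, matrix(rnorm(length(channels) * n, 0, sd),
                                   length(channels), n))
  new_recording(X, fs, channels)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}

# hand-built feature_matrix with arbitrary values for dataset-level tests
fake_feature_matrix <- function(values, meta, fs = 200) {
  structure(list(values = values, meta = meta, fs = fs,
                 spec = window_spec()),
            class = "feature_matrix")
}

# a synthetic flat one-sided spectrum of height `c` per 1 Hz bin
flat_spectrum <- function(c = 1, fmax = 125, channels = 1) {
  structure(list(freq = 0:fmax,
                 power = matrix(c, fmax + 1, channels),
                 df = 1),
            class = "eeg_spectrum")
}

# normalized per-subject feature list for assembly tests: k features,
# values drawn from N(class_mean, 1) so tables are usable by classifiers
fake_cohort_features <- function(n_subjects = 2, windows_per_event = 8,
                                 k = 3, seed = 1) {
  cfg <- tiny_config(n_subjects = max(n_subjects, 2), seed = seed)
  sched <- subject_schedule(cfg)
  with_seed_test(seed, lapply(seq_len(n_subjects), function(s) {
    rows <- list(); meta <- list()
    for (e in which(sched$kind != "cross")) {
      V <- matrix(rnorm(windows_per_event * k, mean = sched$load[e]),
                  windows_per_event, k,
                  dimnames = list(NULL, paste0("FZ__f", seq_len(k))))
      rows[[length(rows) + 1L]] <- V
      meta[[length(meta) + 1L]] <- data.frame(
        event = e, kind = sched$kind[e], label = sched$label[e],
        trial = sched$trial[e],
        t_mid = sched$onset[e] + seq_len(windows_per_event) * 0.2)
    }
    list(subject = s,
         fm = fake_feature_matrix(do.call(rbind, rows), do.call(rbind, meta)),
         tlx = data.frame(task = c("C1", "C2", "C3"), score = c(2, 5, 5)))
  }))
}

# brute-force two-sided Mann-Whitney p by enumerating all label
# assignments (oracle; n1 + n2 choose n1 assignments)
mw_exact_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  v <- c(x, y)
  r <- rank(v)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = p)
}
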