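# Per-window feature engineering: 8 time-domain features per channel,
# 40 frequency-domain features per channel, and 127 multi-channel features
# (3007 named features on the 60-channel montage).

#' Enumerate sliding windows inside an event
#'
#' Windows of `spec$length` seconds advanced by `spec$hop` seconds, fully
#' contained in the event. Arithmetic is carried out in integer samples so
#' the count is exactly `floor((D - length)/hop) + 1`.
#'
#' @param rec An `eeg_recording` (for `fs` and bounds).
#' @param spec A [window_spec()].
#' @param event One row of an `event_schedule` (or a list with `onset`,
#'   `duration`, in seconds).
#' @return data.frame with `start` (sample index, 1-based), `end`, `t_mid`
#'   (seconds).
#' @export
sliding_windows <- function(rec, spec, event) {
  L <- as.integer(round(spec$length * rec$fs))
  hop <- as.integer(round(spec$hop * rec$fs))
  if (hop < 1) stop_cogload("hop shorter than one sample")
  n_ev <- as.integer(round(event$duration * rec$fs))
  if (n_ev < L)
    stop_cogload("event '%s' at %gs is shorter (%gs) than one window (%gs)",
                 event$label %||% event$kind %||% "?", event$onset,
                 event$duration, spec$length)
  i0 <- as.integer(round(event$onset * rec$fs)) + 1L
  k <- (n_ev - L) %/% hop + 1L
  start <- i0 + (seq_len(k) - 1L) * hop
  data.frame(start = start, end = start + L - 1L,
             t_mid = (start - 1L + L / 2) / rec$fs)
}

# --- single-window primitives ----------------------------------------------

#' Time-domain features of a window
#'
#' Eight features per channel: mean of the raw signal, mean of the min-max
#' normalized signal, variance, skewness, kurtosis, and the three Hjorth
#' parameters (activity, mobility, complexity). Activity duplicates the
#' variance by construction (intentional redundancy so the per-channel
#' count is 8). Skewness and kurtosis use biased moment estimators;
#' kurtosis is raw (non-excess). Hjorth derivatives are first differences
#' scaled by `fs`, giving mobility in rad/s (a pure sinusoid of frequency f
#' has mobility 2*pi*f and complexity 1). Zero-variance channels return 0
#' for the guarded features, with a `flags` attribute.
#'
#' @param X Channels x samples matrix (or a vector, one channel); >= 3
#'   samples.
#' @param fs Sampling rate in Hz.
#' @return Channels x 8 matrix with feature column names and a logical
#'   `flags` attribute marking guarded channels.
#' @export
time_domain_features <- function(X, fs) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  L <- ncol(X)
  if (L < 3) stop_cogload("window must have >= 3 samples")
  mu <- rowMeans(X)
  Xc <- X - mu
  m2 <- rowMeans(Xc^2)
  m3 <- rowMeans(Xc^3)
  m4 <- rowMeans(Xc^4)
  mn <- apply(X, 1, min)
  mx <- apply(X, 1, max)
  flat <- m2 < 1e-24
  rng0 <- (mx - mn) < 1e-12
  mean_norm <- ifelse(rng0, 0.5, (mu - mn) / (mx - mn))
  skew <- ifelse(flat, 0, m3 / m2^1.5)
  kurt <- ifelse(flat, 0, m4 / m2^2)
  d1 <- (X[, -1, drop = FALSE] - X[, -L, drop = FALSE]) * fs
  v1 <- rowMeans(d1^2) - rowMeans(d1)^2
  d2 <- (d1[, -1, drop = FALSE] - d1[, -(L - 1), drop = FALSE]) * fs
  v2 <- rowMeans(d2^2) - rowMeans(d2)^2
  mob <- ifelse(flat | v1 <= 0, 0, sqrt(v1 / m2))
  mob_d <- ifelse(v1 <= 0 | v2 <= 0, 0, sqrt(v2 / v1))
  comp <- ifelse(mob <= 0, 0, mob_d / mob)
  out <- cbind(mean_raw = mu, mean_norm = mean_norm, variance = m2,
               skewness = skew, kurtosis = kurt,
               hjorth_activity = m2, hjorth_mobility = mob,
               hjorth_complexity = comp)
  attr(out, "flags") <- flat
  out
}

#' One-sided periodogram of a window
#'
#' PSD computed as the squared magnitude of the FFT, one-sided, normalized
#' so that the sum over the non-zero-frequency bins equals the (biased)
#' signal variance (Parseval). At the default 1-second window the frequency
#' resolution is exactly 1 Hz.
#'
#' @param X Channels x samples matrix (or vector).
#' @param fs Sampling rate in Hz.
#' @return List of class `eeg_spectrum`: `freq` (Hz), `power`
#'   (bins x channels), `df` (bin width, Hz).
#' @export
psd <- function(X, fs) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  L <- ncol(X)
  FT <- stats::mvfft(t(X))
  kmax <- L %/% 2
  p <- Mod(FT[seq_len(kmax + 1), , drop = FALSE])^2 / L^2
  scale <- rep(2, kmax + 1)
  scale[1] <- 1
  if (L %% 2 == 0) scale[kmax + 1] <- 1
  p <- p * scale
  structure(list(freq = (0:kmax) * fs / L, power = p, df = fs / L),
            class = "eeg_spectrum")
}

#' Band powers from a spectrum
#'
#' Absolute power is the area under the PSD over each half-open band
#' `[low, high)`; total power is the area over `[0, 90)` Hz; relative power
#' is absolute/total (0, flagged, for an empty spectrum). The seven default
#' bands partition `[0, 90)`, so relative powers sum to 1.
#'
#' @param spectrum An `eeg_spectrum` from [psd()].
#' @param bands Band table from [eeg_bands()].
#' @return List of class `band_powers`: `total` (per channel), `absolute`
#'   and `relative` (bands x channels matrices), `bands`.
#' @export
band_powers <- function(spectrum, bands = eeg_bands()) {
  f <- spectrum$freq
  if (max(bands$high) > max(f) + spectrum$df / 2)
    stop_cogload("spectrum range (%g Hz) below highest band edge (%g Hz)",
                 max(f), max(bands$high))
  p <- spectrum$power
  M <- vapply(seq_len(nrow(bands)),
              function(b) as.numeric(f >= bands$low[b] & f < bands$high[b]),
              numeric(length(f)))
  absolute <- t(M) %*% p * spectrum$df
  rownames(absolute) <- bands$name
  total <- colSums(p[f >= 0 & f < 90, , drop = FALSE]) * spectrum$df
  zero <- total <= 0
  relative <- sweep(absolute, 2, ifelse(zero, 1, total), "/")
  relative[, zero] <- 0
  structure(list(total = total, absolute = absolute, relative = relative,
                 bands = bands$name, flags = zero),
            class = "band_powers")
}

#' Pairwise band-power ratios
#'
#' All C(7,2) = 21 ratios of absolute band powers, numerator before
#' denominator in canonical band order (Delta, Theta, Alpha, Beta,
#' LowGamma, MediumGamma, HighGamma). Denominators are epsilon-guarded at
#' `1e-12 * total power`.
#'
#' @param powers A `band_powers` object.
#' @return 21 x channels matrix with ratio names `<num>_<den>`.
#' @export
band_ratios <- function(powers) {
  ab <- powers$absolute
  nb <- nrow(ab)
  eps <- pmax(1e-12 * powers$total, 1e-300)
  combs <- utils::combn(nb, 2)
  out <- matrix(0, ncol(combs), ncol(ab))
  nm <- character(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    out[k, ] <- ab[i, ] / pmax(ab[j, ], eps)
    nm[k] <- paste0(powers$bands[i], "_", powers$bands[j])
  }
  rownames(out) <- nm
  out
}

#' Task-engagement indexes
#'
#' The two classic engagement ratios of absolute band powers:
#' `index1 = beta / (theta + alpha)` and `index2 = theta / (beta + alpha)`,
#' with epsilon-guarded denominators.
#'
#' @param powers A `band_powers` object.
#' @return 2 x channels matrix with rows `index1`, `index2`.
#' @export
engagement_indexes <- function(powers) {
  ab <- powers$absolute
  eps <- pmax(1e-12 * powers$total, 1e-300)
  i1 <- ab["Beta", ] / pmax(ab["Theta", ] + ab["Alpha", ], eps)
  i2 <- ab["Theta", ] / pmax(ab["Beta", ] + ab["Alpha", ], eps)
  rbind(index1 = i1, index2 = i2)
}

#' Spectral centroid and alpha peak frequency
#'
#' Average frequency is the power-weighted centroid over `[1, 90)` Hz;
#' alpha peak frequency is the frequency of the maximum PSD bin within the
#' alpha band `[8, 13)`, ties broken toward the lowest frequency. A zero
#' spectrum yields 0 (flagged).
#'
#' @param spectrum An `eeg_spectrum`.
#' @return 2 x channels matrix with rows `avgfreq`, `alphapeak`.
#' @export
spectral_summaries <- function(spectrum) {
  f <- spectrum$freq
  p <- spectrum$power
  m <- f >= 1 & f < 90
  tot <- colSums(p[m, , drop = FALSE])
  avg <- ifelse(tot > 0, colSums(p[m, , drop = FALSE] * f[m]) / pmax(tot, 1e-300), 0)
  ma <- f >= 8 & f < 13
  fa <- f[ma]
  pa <- p[ma, , drop = FALSE]
  peak <- fa[apply(pa, 2, which.max)]          # which.max: first (lowest) tie
  peak[colSums(pa) <= 0] <- 0
  rbind(avgfreq = avg, alphapeak = peak)
}

#' Hemispheric asymmetry features
#'
#' Differential (left - right) and rational (left / right, guarded)
#' asymmetry of absolute band powers for homologous electrode pairs:
#' `pairs x bands x 2` features (126 at the default 9 pairs and 7 bands).
#'
#' @param powers A `band_powers` object whose columns are named channels.
#' @param pairs data.frame with columns `left`, `right`
#'   (default [asymmetry_pairs_default()]).
#' @return Named numeric vector of length `2 * nrow(pairs) * n_bands`.
#' @export
asymmetry_features <- function(powers, pairs = asymmetry_pairs_default()) {
  ab <- powers$absolute
  chans <- colnames(ab)
  miss <- setdiff(c(pairs$left, pairs$right), chans)
  if (length(miss))
    stop_cogload("montage missing asymmetry electrode(s): %s",
                 paste(miss, collapse = ", "))
  out <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    l <- ab[, pairs$left[k]]; r <- ab[, pairs$right[k]]
    eps <- pmax(1e-12 * (l + r), 1e-300)
    v <- c(l - r, l / pmax(r, eps))
    names(v) <- c(paste0(pairs$left[k], "_", pairs$right[k], "__dasym__", powers$bands),
                  paste0(pairs$left[k], "_", pairs$right[k], "__rasym__", powers$bands))
    out <- c(out, v)
  }
  out
}

#' Frontal-parietal "Brainbeat" cognitive-load index
#'
#' Ratio of the absolute theta power at Fz to the absolute alpha power at
#' Pz, epsilon-guarded.
#'
#' @param powers A `band_powers` object with named channel columns
#'   including FZ and PZ.
#' @return A single numeric value.
#' @export
brainbeat <- function(powers) {
  chans <- colnames(powers$absolute)
  if (!all(c("FZ", "PZ") %in% chans))
    stop_cogload("brainbeat needs channels FZ and PZ")
  th <- powers$absolute["Theta", "FZ"]
  al <- powers$absolute["Alpha", "PZ"]
  eps <- max(1e-12 * powers$total[["PZ"]], 1e-300)
  unname(th / max(al, eps))
}

# --- full extraction --------------------------------------------------------

# canonical feature names for a montage
feature_names <- function(labels, bands = eeg_bands(),
                          pairs = asymmetry_pairs_default()) {
  td <- c("mean_raw", "mean_norm", "variance", "skewness", "kurtosis",
          "hjorth_activity", "hjorth_mobility", "hjorth_complexity")
  combs <- utils::combn(nrow(bands), 2)
  rnames <- apply(combs, 2, function(ij)
    paste0(bands$name[ij[1]], "_", bands$name[ij[2]]))
  fd <- c("totalpow",
          paste0("abspow__", bands$name),
          paste0("relpow__", bands$name),
          paste0("ratio__", rnames),
          "index1", "index2", "avgfreq", "alphapeak")
  # per pair: dasym over the 7 bands, then rasym over the 7 bands
  multi <- c(unlist(lapply(seq_len(nrow(pairs)), function(k) {
    pr <- paste0(pairs$left[k], "_", pairs$right[k])
    c(paste0(pr, "__dasym__", bands$name), paste0(pr, "__rasym__", bands$name))
  })), "FZ_PZ__brainbeat")
  c(as.vector(vapply(labels, function(ch) paste0(ch, "__", td), character(8))),
    as.vector(vapply(labels, function(ch) paste0(ch, "__", fd), character(40))),
    multi)
}

#' Extract the full feature matrix of a recording
#'
#' Runs the sliding-window feature engineering over every event of the
#' schedule: per window, 8 time-domain features and 40 frequency-domain
#' features per channel plus the multi-channel asymmetry and Brainbeat
#' features. On the 60-channel montage with the default 9 pairs this is
#' 480 + 2400 + 127 = 3007 uniquely named columns.
#'
#' @param rec An `eeg_recording` containing the required electrodes.
#' @param spec A [window_spec()] (default 1 s, 80% overlap).
#' @param schedule An `event_schedule` aligned with the recording.
#' @param bands,pairs Band and asymmetry-pair definitions.
#' @param kinds Event kinds to extract windows from.
#' @return Object of class `feature_matrix`: `values` (windows x features),
#'   `meta` (data.frame `event`, `kind`, `label`, `trial`, `t_mid`), and
#'   `fs`, `spec`.
#' @export
extract_all <- function(rec, spec = window_spec(), schedule,
                        bands = eeg_bands(),
                        pairs = asymmetry_pairs_default(),
                        kinds = c("cross", "reading", "code")) {
  stopifnot(inherits(rec, "eeg_recording"))
  need <- unique(c(pairs$left, pairs$right, "FZ", "PZ"))
  miss <- setdiff(need, rec$labels)
  if (length(miss))
    stop_cogload("montage missing electrode(s): %s", paste(miss, collapse = ", "))
  fn <- feature_names(rec$labels, bands, pairs)
  evs <- which(schedule$kind %in% kinds)
  winlist <- lapply(evs, function(e) {
    w <- sliding_windows(rec, spec, schedule[e, ])
    w$event <- e
    w
  })
  wins <- do.call(rbind, winlist)
  nw <- nrow(wins)
  V <- matrix(NA_real_, nw, length(fn))
  colnames(V) <- fn
  C <- length(rec$labels)
  # cached band masks for the window length
  L <- as.integer(round(spec$length * rec$fs))
  for (i in seq_len(nw)) {
    X <- rec$data[, wins$start[i]:wins$end[i], drop = FALSE]
    td <- time_domain_features(X, rec$fs)
    sp <- psd(X, rec$fs)
    colnames(sp$power) <- rec$labels
    bp <- band_powers(sp, bands)
    colnames(bp$absolute) <- rec$labels
    rat <- band_ratios(bp)
    eng <- engagement_indexes(bp)
    ss <- spectral_summaries(sp)
    freq_block <- rbind(totalpow = bp$total, bp$absolute, bp$relative,
                        rat, eng, ss)
    V[i, ] <- c(as.vector(t(td)),            # channel-major time block
                as.vector(freq_block),       # channel-major freq block
                asymmetry_features(bp, pairs),
                brainbeat(bp))
  }
  meta <- data.frame(event = wins$event,
                     kind = schedule$kind[wins$event],
                     label = schedule$label[wins$event],
                     trial = schedule$trial[wins$event],
                     t_mid = wins$t_mid,
                     stringsAsFactors = FALSE)
  structure(list(values = V, meta = meta, fs = rec$fs, spec = spec),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
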