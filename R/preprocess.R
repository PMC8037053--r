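# Preprocessing: zero-phase FIR filtering, bad-channel handling,
# average re-reference, gross-artifact segment rejection.
#
# The pipeline order filter -> interpolate -> re-reference -> ICA is
# enforced through the recording's history.

has_stage <- function(rec, stage) any(grepl(paste0("^", stage), rec$history))

require_stage <- function(rec, stage, op) {
  if (!has_stage(rec, stage))
    stop_cogload("%s requires '%s' to have been applied first (history: %s)",
                 op, stage, paste(rec$history, collapse = " -> "))
}

forbid_stage <- function(rec, stage, op) {
  if (has_stage(rec, stage))
    stop_cogload("%s must be applied before '%s' (history: %s)",
                 op, stage, paste(rec$history, collapse = " -> "))
}

# Zero-phase application of a symmetric (linear-phase, odd-length) FIR
# kernel via FFT convolution with edge-reflection padding.
fir_zerophase <- function(X, b) {
  lb <- length(b)
  stopifnot(lb %% 2 == 1)
  d <- (lb - 1) / 2
  n <- ncol(X)
  pad <- min(n - 1, lb)
  t(apply(X, 1, function(x) {
    xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
    y <- signal::fftfilt(b, c(xp, numeric(d)))
    y[(pad + d + 1):(pad + d + n)]
  }))
}

# Hamming-window FIR order for a transition bandwidth (normalized heuristic
# N ~ 3.3 / (tb / fs)), forced even, capped below a third of the data length.
fir_order <- function(fs, tb, n_samples) {
  N <- ceiling(3.3 * fs / tb)
  N <- N + N %% 2
  cap <- floor((n_samples - 1) / 3)
  cap <- cap - cap %% 2
  if (N > cap) {
    warn_cogload("FIR order reduced from %d to %d (recording too short)", N, cap)
    N <- cap
  }
  max(N, 4L)
}

#' Band-pass and notch filter an EEG recording
#'
#' Applies, in order: a 1 Hz high-pass (removing DC and slow drifts), a
#' 90 Hz low-pass (the upper limit of the analysis bands), and a 50 Hz
#' notch (powerline) filter. All filters are Hamming-window FIR designs
#' applied zero-phase, so window-aligned features suffer no latency
#' distortion. Transition bandwidths follow the standard Hamming design
#' heuristic and are recorded in the history.
#'
#' @param rec An [new_recording()]; `fs` must be at least 200 Hz.
#' @param hp,lp High-/low-pass cut-offs in Hz.
#' @param notch Notch centre frequency in Hz (0 disables).
#' @param notch_halfwidth Half-width of the notch stop band in Hz.
#' @return The filtered recording, history updated.
#' @export
apply_filters <- function(rec, hp = 1, lp = 90, notch = 50,
                          notch_halfwidth = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs < 200) stop_cogload("fs = %g Hz too low (need >= 200)", rec$fs)
  n <- ncol(rec$data)
  nyq <- rec$fs / 2
  X <- rec$data
  if (hp > 0) {
    Nh <- fir_order(rec$fs, max(hp, 0.5), n)
    bh <- signal::fir1(Nh, hp / nyq, type = "high")
    X <- fir_zerophase(X, bh)
  }
  if (lp > 0) {
    Nl <- fir_order(rec$fs, 0.25 * lp, n)
    bl <- signal::fir1(Nl, lp / nyq, type = "low")
    X <- fir_zerophase(X, bl)
  }
  if (notch > 0) {
    Nn <- fir_order(rec$fs, 1, n)
    bn <- signal::fir1(Nn, c(notch - notch_halfwidth,
                             notch + notch_halfwidth) / nyq, type = "stop")
    X <- fir_zerophase(X, bn)
  }
  rec$data <- X
  add_history(rec, sprintf("filter(hp=%g,lp=%g,notch=%g)", hp, lp, notch))
}

#' Detect flat or noisy channels
#'
#' Flags channels whose standard deviation is below `flat_tol` (flat /
#' disconnected) or whose log-variance robust z-score (median/MAD over
#' channels) exceeds `z_thresh` (noisy).
#'
#' @param rec An `eeg_recording` with at least 8 channels.
#' @param flat_tol Flat threshold in microvolts (on the SD scale).
#' @param z_thresh Robust z-score threshold on log variance.
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, flat_tol = 0.1, z_thresh = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 8) stop_cogload("need >= 8 channels")
  v <- apply(rec$data, 1, stats::var)
  flat <- sqrt(v) < flat_tol
  lv <- log(pmax(v, 1e-300))
  med <- stats::median(lv[!flat])
  s <- stats::mad(lv[!flat])
  z <- if (s > 0) (lv - med) / s else rep(0, length(lv))
  noisy <- !flat & z > z_thresh
  rec$labels[flat | noisy]
}

# Legendre polynomial values P_1..P_nmax at x (vector), as a matrix
# length(x) x nmax, by the three-term recurrence.
legendre_terms <- function(x, nmax) {
  P <- matrix(0, length(x), nmax)
  P[, 1] <- x
  if (nmax >= 2) P[, 2] <- (3 * x^2 - 1) / 2
  if (nmax >= 3) for (nn in 3:nmax)
    P[, nn] <- ((2 * nn - 1) * x * P[, nn - 1] - (nn - 1) * P[, nn - 2]) / nn
  P
}

# Perrin spherical-spline kernel g(cos(angle)) with stiffness m.
spline_g <- function(cosang, m = 4, nmax = 20) {
  nn <- seq_len(nmax)
  coef <- (2 * nn + 1) / (nn * (nn + 1))^m
  P <- legendre_terms(pmin(pmax(cosang, -1), 1), nmax)
  drop(P %*% coef) / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the listed channels with spherical-spline estimates (stiffness
#' m = 4) computed from the remaining channels' unit-sphere positions.
#' Good channels are untouched.
#'
#' @param rec A filtered `eeg_recording`.
#' @param bad Character vector of channel labels to replace.
#' @param m Spline stiffness (default 4).
#' @param lambda Ridge regularization of the spline system.
#' @return The recording with interpolated channels, history updated.
#' @export
interpolate_channels <- function(rec, bad, m = 4, lambda = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad) == 0) return(rec)
  require_stage(rec, "filter", "interpolate_channels")
  forbid_stage(rec, "rereference", "interpolate_channels")
  bad <- toupper(bad)
  miss <- setdiff(bad, rec$labels)
  if (length(miss)) stop_cogload("unknown channel(s): %s", paste(miss, collapse = ", "))
  pos <- rec$positions
  usable <- !is.na(pos$x)
  good <- rec$labels[usable & !(rec$labels %in% bad)]
  if (length(good) < 4) stop_cogload("need >= 4 good channels with positions")
  P <- as.matrix(pos[match(good, pos$label), c("x", "y", "z")])
  Q <- as.matrix(pos[match(bad, pos$label), c("x", "y", "z")])
  G <- spline_g(tcrossprod(P), m = m)
  dim(G) <- c(nrow(P), nrow(P))
  Gq <- spline_g(Q %*% t(P), m = m)
  dim(Gq) <- c(nrow(Q), nrow(P))
  ng <- length(good)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  Y <- rbind(rec$data[good, , drop = FALSE], 0)
  sol <- solve(A, Y)                      # spline weights + constant
  est <- Gq %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], nrow(Q), ncol(rec$data), byrow = TRUE)
  rec$data[bad, ] <- est
  add_history(rec, sprintf("interpolate(%s)", paste(bad, collapse = ",")))
}

#' Re-reference to the channel average
#'
#' Subtracts, at every sample, the mean over all channels. Idempotent; the
#' output channel mean is zero at every sample.
#'
#' @param rec An `eeg_recording`.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  add_history(rec, "rereference(average)")
}

#' Flag gross-amplitude segments before ICA
#'
#' Marks intervals where any channel exceeds `amp_thresh` in absolute
#' amplitude (non-stationary bursts, large muscle activity). The samples
#' stay in the timeline; the flagged intervals are excluded from ICA
#' fitting.
#'
#' @param rec An `eeg_recording`.
#' @param amp_thresh Amplitude threshold in microvolts (> 0; `Inf` flags
#'   nothing).
#' @param pad Seconds of padding added around each flagged sample run.
#' @return The recording with attribute-like element `rejected_intervals`
#'   (data.frame `start`, `end` in seconds).
#' @export
reject_gross_segments <- function(rec, amp_thresh = 200, pad = 0.25) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(amp_thresh > 0)) stop_cogload("amp_thresh must be > 0")
  hit <- apply(abs(rec$data) > amp_thresh, 2, any)
  iv <- data.frame(start = numeric(), end = numeric())
  if (any(hit)) {
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    iv <- data.frame(start = pmax((starts[keep] - 1) / rec$fs - pad, 0),
                     end = pmin(ends[keep] / rec$fs + pad, rec_duration(rec)))
    # merge overlapping padded intervals
    if (nrow(iv) > 1) {
      merged <- iv[1, ]
      for (i in 2:nrow(iv)) {
        if (iv$start[i] <= merged$end[nrow(merged)]) {
          merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], iv$end[i])
        } else merged <- rbind(merged, iv[i, ])
      }
      iv <- merged
    }
    if (sum(iv$end - iv$start) >= rec_duration(rec))
      stop_cogload("all data rejected at amp_thresh = %g", amp_thresh)
  }
  rec$rejected_intervals <- iv
  add_history(rec, sprintf("reject(amp=%g,n=%d)", amp_thresh, nrow(iv)))
}

# logical mask of samples retained after gross-segment rejection
clean_sample_mask <- function(rec) {
  keep <- rep(TRUE, ncol(rec$data))
  iv <- rec$rejected_intervals
  if (!is.null(iv) && nrow(iv)) {
    for (i in seq_len(nrow(iv))) {
      a <- max(1L, time_to_sample(rec, iv$start[i]))
      b <- min(ncol(rec$data), time_to_sample(rec, iv$end[i]))
      keep[a:b] <- FALSE
    }
  }
  keep
}
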