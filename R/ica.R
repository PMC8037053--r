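# Extended-Infomax independent component analysis and automated artifact
# component flagging/removal.

#' Fit an extended-Infomax ICA decomposition
#'
#' Blind source separation of the (cleaned, average-referenced) recording.
#' The data are centred and PCA-whitened; rank-deficient inputs (average
#' reference removes one degree of freedom) automatically yield
#' rank-many components. The extended-Infomax natural-gradient rule with
#' a per-component sub/super-Gaussian sign (re-estimated from the kurtosis
#' of the component activations) is then iterated in randomized blocks with
#' learning-rate annealing. Deterministic under a fixed seed.
#'
#' @param rec An average-referenced `eeg_recording`; samples flagged by
#'   [reject_gross_segments()] are excluded from fitting.
#' @param n_components Number of components; default the numerical rank of
#'   the data (channels - 1 after average reference).
#' @param seed Integer seed for block shuffling and initialization.
#' @param max_iter Maximum training epochs.
#' @param tol Stop when the Frobenius norm of the weight update falls
#'   below this.
#' @param require_rereference Set FALSE to fit on non-average-referenced
#'   data (the standard pipeline re-references first).
#' @return An object of class `ica_decomposition`: `unmixing`
#'   (components x channels, including whitening), `mixing`
#'   (channels x components), `activations` (components x samples, full
#'   timeline), `center`, `labels`, `fs`, `n_components`.
#' @export
fit_ica <- function(rec, n_components = NULL, seed = 1L, max_iter = 200,
                    tol = 1e-7, require_rereference = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (require_rereference) require_stage(rec, "rereference", "fit_ica")
  keep <- clean_sample_mask(rec)
  X <- rec$data[, keep, drop = FALSE]
  C <- nrow(X); n <- ncol(X)
  if (n < 20 * C^2)
    warn_cogload("only %d clean samples for %d channels (< 20 x channels^2); ICA may be unstable",
                 n, C)
  ctr <- rowMeans(X)
  Xc <- X - ctr
  cv <- tcrossprod(Xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  tol_ev <- max(eg$values) * 1e-9
  rank <- sum(eg$values > tol_ev)
  if (rank < 2) {
    v <- apply(rec$data, 1, stats::var)
    stop_cogload("rank-deficient data (rank %d); offending channels: %s",
                 rank, paste(rec$labels[v < 1e-12], collapse = ", "))
  }
  m <- min(n_components %||% rank, rank)
  if (!is.null(n_components) && n_components > rank)
    warn_cogload("n_components reduced to data rank %d", rank)
  # whitening: m x C
  Wh <- diag(1 / sqrt(eg$values[seq_len(m)])) %*% t(eg$vectors[, seq_len(m), drop = FALSE])
  Z <- Wh %*% Xc
  W <- with_seed(seed, ext_infomax(Z, max_iter = max_iter, tol = tol))
  unmix <- W %*% Wh
  # mixing: pseudo-inverse of the unmixing map
  mix <- eg$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(m)]), m) %*% solve(W)
  acts <- unmix %*% (rec$data - ctr)
  structure(list(unmixing = unmix, mixing = mix, activations = acts,
                 center = ctr, labels = rec$labels, fs = rec$fs,
                 n_components = m),
            class = "ica_decomposition")
}

# Core extended-Infomax loop on whitened data Z (m x n): natural-gradient
# block updates with kurtosis-based sub/super-Gaussian signs and
# learning-rate annealing. Returns the m x m rotation W.
ext_infomax <- function(Z, max_iter = 200, tol = 1e-7, block = NULL,
                        lrate = NULL, anneal = 0.95) {
  m <- nrow(Z); n <- ncol(Z)
  block <- block %||% min(max(floor(sqrt(n / 3)), 8), n)
  lrate <- lrate %||% 0.01 / log(m + 2)
  W <- diag(m)
  signs <- rep(1, m)   # +1 super-Gaussian, -1 sub-Gaussian
  olddelta <- NULL
  for (it in seq_len(max_iter)) {
    oldW <- W
    perm <- sample.int(n)
    nblocks <- max(floor(n / block), 1)
    for (bi in seq_len(nblocks)) {
      idx <- perm[((bi - 1) * block + 1):min(bi * block, n)]
      u <- W %*% Z[, idx, drop = FALSE]
      y <- tanh(u)
      nb <- length(idx)
      grad <- diag(m) - (sweep(y, 1, signs, "*") %*% t(u) + u %*% t(u)) / nb
      W <- W + lrate * grad %*% W
      if (any(!is.finite(W)) || max(abs(W)) > 1e8) {
        W <- diag(m); lrate <- lrate * 0.5; break
      }
    }
    # re-estimate sub/super-Gaussian signs from activation kurtosis
    u <- W %*% Z
    k <- rowMeans(u^4) / (rowMeans(u^2))^2 - 3
    signs <- ifelse(k >= 0, 1, -1)
    delta <- W - oldW
    change <- sqrt(sum(delta^2))
    if (!is.null(olddelta) && change > 0) {
      ang <- sum(delta * olddelta) /
        (sqrt(sum(delta^2)) * sqrt(sum(olddelta^2)) + 1e-30)
      if (ang < 0.5) lrate <- lrate * anneal
    }
    olddelta <- delta
    if (change < tol) break
  }
  W
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components over %d channels\n",
              x$n_components, length(x$labels)))
  invisible(x)
}

# one-sided periodogram of a vector, 1 Hz-ish resolution capped by length
comp_spectrum <- function(a, fs) {
  n <- min(length(a), fs * 4)
  a <- a[seq_len(n)] - mean(a[seq_len(n)])
  p <- Mod(stats::fft(a))^2 / n^2
  kmax <- floor(n / 2)
  f <- (0:kmax) * fs / n
  pw <- p[1:(kmax + 1)] * c(1, rep(2, kmax - 1), 1)
  list(f = f, p = pw)
}

#' Flag artifact components by automated heuristics
#'
#' Scores each independent component for: blinks (frontal topography
#' dominance combined with a high low-frequency power ratio), powerline
#' contamination (50 Hz spectral peak prominence), and muscle activity
#' (positive log-power spectral slope above 30 Hz). Components exceeding
#' any threshold are flagged. Thresholds are configurable; defaults are
#' conservative so clean synthetic data yield an empty list.
#'
#' @param ica An `ica_decomposition`.
#' @param rec The recording the decomposition was fitted on.
#' @param blink_topo Frontal/other mean-absolute-topography ratio threshold.
#' @param blink_lowfreq Low-frequency (< 4 Hz) power-ratio threshold.
#' @param line_prominence 50 Hz peak / local baseline ratio threshold.
#' @param muscle_slope Log-power slope threshold (per Hz) above 30 Hz.
#' @return Integer vector of flagged component indices, with a `scores`
#'   attribute (data.frame of the per-component scores).
#' @export
flag_artifact_components <- function(ica, rec, blink_topo = 3,
                                     blink_lowfreq = 0.55,
                                     line_prominence = 8,
                                     muscle_slope = 0.005) {
  stopifnot(inherits(ica, "ica_decomposition"))
  frontal <- ica$labels %in% c("FP1", "FPZ", "FP2", "AF3", "AF4")
  m <- ica$n_components
  scores <- data.frame(blink = numeric(m), line = numeric(m),
                       muscle = numeric(m))
  flagged <- integer()
  for (i in seq_len(m)) {
    topo <- abs(ica$mixing[, i])
    topo_ratio <- if (any(frontal) && mean(topo[!frontal]) > 0)
      mean(topo[frontal]) / mean(topo[!frontal]) else 0
    sp <- comp_spectrum(ica$activations[i, ], ica$fs)
    tot <- sum(sp$p[sp$f > 0])
    lowr <- if (tot > 0) sum(sp$p[sp$f > 0 & sp$f < 4]) / tot else 0
    in50 <- sp$f >= 49 & sp$f <= 51
    near50 <- (sp$f >= 40 & sp$f < 49) | (sp$f > 51 & sp$f <= 60)
    line_r <- if (any(in50) && mean(sp$p[near50]) > 0)
      max(sp$p[in50]) / mean(sp$p[near50]) else 0
    hi <- sp$f >= 30 & sp$f <= 90 & sp$p > 0
    slope <- if (sum(hi) > 5)
      stats::coef(stats::lm(log(sp$p[hi]) ~ sp$f[hi]))[2] else 0
    scores$blink[i] <- topo_ratio * lowr
    scores$line[i] <- line_r
    scores$muscle[i] <- slope
    if ((topo_ratio > blink_topo && lowr > blink_lowfreq) ||
        line_r > line_prominence || slope > muscle_slope)
      flagged <- c(flagged, i)
  }
  attr(flagged, "scores") <- scores
  flagged
}

#' Remove independent components from a recording
#'
#' Reconstructs the recording without the listed components. An empty
#' index list reproduces the input (round-trip within numerical
#' tolerance).
#'
#' @param rec The `eeg_recording` the ICA was fitted on.
#' @param ica An `ica_decomposition`.
#' @param idx Integer indices of components to remove.
#' @return The cleaned recording, history updated.
#' @export
remove_components <- function(rec, ica, idx) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(ica, "ica_decomposition"))
  if (length(idx) == 0) return(add_history(rec, "ica_remove(none)"))
  idx <- as.integer(idx)
  if (any(idx < 1 | idx > ica$n_components)) stop_cogload("component index out of range")
  if (length(unique(idx)) >= ica$n_components)
    stop_cogload("refusing to remove all %d components", ica$n_components)
  rec$data <- rec$data -
    ica$mixing[, idx, drop = FALSE] %*% ica$activations[idx, , drop = FALSE]
  add_history(rec, sprintf("ica_remove(%s)", paste(idx, collapse = ",")))
}
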