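# Space-time localization of cognitive load: gaze density, 3-D density
# clustering, AOI mapping, EEG feature time-courses, and the critical-
# region hypothesis test.

#' Row-wise gaze density profile
#'
#' Histogram of gaze y-coordinates over rows of `row_height` pixels, with
#' the reference level at 50% of the maximum row density.
#'
#' @param gaze A `gaze_stream` (>= 1 valid point).
#' @param row_height Row height in pixels.
#' @return List `breaks` (bin edges), `counts`, `reference`
#'   (0.5 * max count).
#' @export
gaze_density_profile <- function(gaze, row_height = 28) {
  g <- gaze[gaze$valid, , drop = FALSE]
  if (nrow(g) == 0) stop_cogload("gaze stream has no valid points")
  lo <- floor(min(g$y) / row_height) * row_height
  hi <- ceiling(max(g$y) / row_height + 1e-9) * row_height
  if (hi <= lo) hi <- lo + row_height
  breaks <- seq(lo, hi, by = row_height)
  counts <- graphics::hist(g$y, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  list(breaks = breaks, counts = counts, reference = max(counts) / 2)
}

# plain DBSCAN on a points-in-rows matrix (Euclidean, O(n^2) distances)
dbscan_core <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  labels <- rep(0L, n)          # 0 = unvisited/noise
  visited <- rep(FALSE, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- which(D[i, ] <= eps)
    if (length(nb) < min_pts) next       # noise (may be claimed later)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nb2 <- which(D[j, ] <= eps)
        if (length(nb2) >= min_pts) queue <- c(queue, setdiff(nb2, which(visited)))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

#' Density-based clustering of gaze points
#'
#' DBSCAN in the three-dimensional feature space (time instant,
#' y-coordinate, distance between consecutive gaze points). Because the
#' raw units are incommensurable, each dimension is z-scored before
#' distance computation. Label 0 marks noise points. Deterministic given
#' the inputs; invariant to uniform time translation.
#'
#' @param gaze A `gaze_stream` with at least `min_pts` valid points.
#' @param eps DBSCAN radius in standardized units (default 0.5).
#' @param min_pts Core-point neighborhood size (default 10).
#' @return Integer cluster labels (0 = noise), one per valid gaze point,
#'   with attribute `features` (the standardized 3-D matrix).
#' @export
cluster_gaze <- function(gaze, eps = 0.5, min_pts = 10) {
  g <- gaze[gaze$valid, , drop = FALSE]
  if (nrow(g) < min_pts)
    stop_cogload("need >= %d valid points, got %d", min_pts, nrow(g))
  dxy <- c(0, sqrt(diff(g$x)^2 + diff(g$y)^2))
  F3 <- cbind(t = g$t, y = g$y, d = dxy)
  sds <- apply(F3, 2, stats::sd)
  sds[sds < 1e-12] <- 1
  Z <- sweep(sweep(F3, 2, colMeans(F3)), 2, sds, "/")
  labels <- dbscan_core(Z, eps = eps, min_pts = min_pts)
  attr(labels, "features") <- Z
  labels
}

#' Map gaze points to AOI regions
#'
#' Labels each gaze point with the AOI whose y-interval contains it;
#' points outside all AOIs get NA. Overlapping AOIs are resolved in favor
#' of the smallest containing region.
#'
#' @param gaze A `gaze_stream`.
#' @param aois An `aoi_set`.
#' @return Character vector of region names (NA outside all regions).
#' @export
map_gaze_to_aoi <- function(gaze, aois) {
  if (is.null(aois) || nrow(aois) == 0) stop_cogload("AOI set is empty")
  heights <- aois$y_max - aois$y_min
  out <- rep(NA_character_, nrow(gaze))
  ord <- order(heights, decreasing = TRUE)  # smaller regions override
  for (k in ord) {
    inside <- gaze$y >= aois$y_min[k] & gaze$y < aois$y_max[k]
    out[inside] <- aois$name[k]
  }
  out
}

#' Baseline-normalized EEG load time-courses
#'
#' Per-window band-power ratios at the two discriminant fronto-parietal
#' targets -- theta/(beta+alpha) at F2 and theta/alpha at Pz by default --
#' for every code event, normalized against the event's preceding fixation
#' cross (the same relative-variation transform used for the feature
#' matrix).
#'
#' @param rec An `eeg_recording` containing the target electrodes.
#' @param spec A [window_spec()].
#' @param schedule The `event_schedule`.
#' @param targets List of targets, each `list(channel=, num=, den=)` with
#'   band names for numerator and denominator (denominator powers are
#'   summed).
#' @param smooth Moving-average half-width in windows (0 = off, default).
#' @return data.frame with columns `target`, `event`, `label`, `t_mid`,
#'   `t_start`, `t_end`, `value` (class `feature_timecourse`).
#' @export
feature_timecourse <- function(rec, spec = window_spec(), schedule,
                               targets = list(
                                 F2 = list(channel = "F2", num = "Theta",
                                           den = c("Beta", "Alpha")),
                                 PZ = list(channel = "PZ", num = "Theta",
                                           den = "Alpha")),
                               smooth = 0) {
  chans <- vapply(targets, function(t) toupper(t$channel), character(1))
  miss <- setdiff(chans, rec$labels)
  if (length(miss))
    stop_cogload("missing electrode(s): %s", paste(miss, collapse = ", "))
  bands <- eeg_bands()
  # raw ratio per window for one event interval
  event_series <- function(e) {
    w <- sliding_windows(rec, spec, schedule[e, ])
    vals <- matrix(NA_real_, nrow(w), length(targets))
    for (i in seq_len(nrow(w))) {
      X <- rec$data[chans, w$start[i]:w$end[i], drop = FALSE]
      sp <- psd(X, rec$fs)
      colnames(sp$power) <- chans
      bp <- band_powers(sp, bands)
      colnames(bp$absolute) <- chans
      for (j in seq_along(targets)) {
        tg <- targets[[j]]
        num <- bp$absolute[tg$num, chans[j]]
        den <- sum(bp$absolute[tg$den, chans[j]])
        eps <- max(1e-12 * bp$total[[chans[j]]], 1e-300)
        vals[i, j] <- num / max(den, eps)
      }
    }
    list(w = w, vals = vals)
  }
  out <- list()
  code_ev <- which(schedule$kind == "code")
  L <- spec$length
  for (e in code_ev) {
    ce <- preceding_cross(schedule, e)
    base <- event_series(ce)
    task <- event_series(e)
    for (j in seq_along(targets)) {
      b <- mean(base$vals[, j])
      v <- if (abs(b) > 1e-12) (task$vals[, j] - b) / b else task$vals[, j] * 0
      if (smooth > 0)
        v <- stats::filter(v, rep(1 / (2 * smooth + 1), 2 * smooth + 1),
                           sides = 2)
      out[[length(out) + 1L]] <- data.frame(
        target = names(targets)[j] %||% chans[j],
        event = e, label = schedule$label[e],
        t_mid = task$w$t_mid, t_start = task$w$t_mid - L / 2,
        t_end = task$w$t_mid + L / 2, value = as.numeric(v),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("feature_timecourse", "data.frame")
  res
}

# Assign each EEG window to inside/outside the critical AOIs by the
# majority of its time-overlapping gaze points; windows without gaze are
# unassigned (NA).
assign_windows <- function(t_start, t_end, gaze, aois) {
  lab <- map_gaze_to_aoi(gaze, aois)
  crit <- !is.na(lab) & aois$critical[match(lab, aois$name)]
  vapply(seq_along(t_start), function(i) {
    sel <- gaze$t >= t_start[i] & gaze$t < t_end[i] & gaze$valid
    if (!any(sel)) return(NA)
    mean(crit[sel]) > 0.5
  }, logical(1))
}

#' Test whether critical code regions carry higher cognitive load
#'
#' Each EEG feature window is assigned inside/outside the critical AOIs by
#' the majority of its time-overlapping gaze points (windows without gaze
#' are excluded). Normality of both groups is checked with Shapiro-Wilk at
#' alpha = 0.05; if either group is non-normal the two groups are compared
#' with a two-sided Mann-Whitney U test, otherwise with a Welch t-test
#' (flagged as a deviation from the rank-based default). The null
#' hypothesis is that the EEG load feature cannot differentiate critical
#' from non-critical code regions.
#'
#' @param timecourse A [feature_timecourse()] data.frame (one or more
#'   targets).
#' @param gaze The `gaze_stream` synchronized with the recording.
#' @param aois The `aoi_set` with critical flags.
#' @param alpha Significance level (default 0.05).
#' @return data.frame per target: `target`, `n_inside`, `n_outside`,
#'   `normal_inside`, `normal_outside`, `method`, `statistic`, `p_value`,
#'   `reject_h0`.
#' @export
critical_region_test <- function(timecourse, gaze, aois, alpha = 0.05) {
  out <- list()
  for (tg in unique(timecourse$target)) {
    tc <- timecourse[timecourse$target == tg, , drop = FALSE]
    grp <- assign_windows(tc$t_start, tc$t_end, gaze, aois)
    xi <- tc$value[!is.na(grp) & grp]
    xo <- tc$value[!is.na(grp) & !grp]
    xi <- xi[is.finite(xi)]; xo <- xo[is.finite(xo)]
    if (length(xi) < 3 || length(xo) < 3)
      stop_cogload("target %s: groups too small (inside %d, outside %d of %d windows)",
                   tg, length(xi), length(xo), nrow(tc))
    sw <- function(v) {
      v <- v[seq_len(min(length(v), 5000))]
      if (stats::sd(v) < 1e-12) return(FALSE)
      stats::shapiro.test(v)$p.value >= alpha
    }
    ni <- sw(xi); no <- sw(xo)
    if (!ni || !no) {
      tst <- mw_u_test(xi, xo)
      method <- "mann-whitney"; stat <- tst$u; p <- tst$p
    } else {
      tst <- stats::t.test(xi, xo)
      method <- "welch-t"; stat <- unname(tst$statistic); p <- tst$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      target = tg, n_inside = length(xi), n_outside = length(xo),
      normal_inside = ni, normal_outside = no, method = method,
      statistic = stat, p_value = p, reject_h0 = p < alpha,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
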