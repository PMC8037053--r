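# Baseline normalization, task segmentation, second-order features and
# sample-table assembly (binary and multiclass labeling schemes).

# index of the fixation cross immediately preceding event `e` in `schedule`
preceding_cross <- function(schedule, e) {
  cand <- which(schedule$kind == "cross" & schedule$onset < schedule$onset[e])
  if (!length(cand))
    stop_cogload("event %d ('%s') has no preceding fixation cross",
                 e, schedule$label[e])
  cand[which.max(schedule$onset[cand])]
}

#' Baseline-normalize a feature matrix against fixation crosses
#'
#' Each task window's feature value is replaced by its relative variation
#' with respect to the mean of that feature over the fixation cross
#' immediately preceding the task in the same run:
#' `delta = (value - baseline_mean) / baseline_mean`. The first cross of a
#' trial normalizes the reading task, the second the code task. Cross
#' windows are consumed as baselines and dropped from the output.
#'
#' Features whose baseline mean is smaller in magnitude than
#' `guard * scale` (scale = the feature's mean absolute value over all
#' baselines) are set to 0 and flagged: near-zero baselines are legitimate
#' for asymmetry features and the ratio would otherwise explode.
#'
#' @param fm A `feature_matrix` from [extract_all()] including cross
#'   windows.
#' @param schedule The `event_schedule` the features were extracted from.
#' @param guard Relative magnitude threshold for the baseline guard.
#' @return A `feature_matrix` with task windows only, values normalized;
#'   element `guard_flags` is a logical matrix marking guarded cells.
#' @export
baseline_normalize <- function(fm, schedule, guard = 1e-9) {
  stopifnot(inherits(fm, "feature_matrix"))
  task_ev <- sort(unique(fm$meta$event[fm$meta$kind != "cross"]))
  if (!length(task_ev)) stop_cogload("no task windows to normalize")
  scale <- mean(abs(fm$values[fm$meta$kind == "cross", , drop = FALSE]))
  if (!is.finite(scale) || scale == 0) scale <- 1
  out <- NULL
  meta <- NULL
  flags <- NULL
  for (e in task_ev) {
    ce <- preceding_cross(schedule, e)
    base_rows <- fm$meta$event == ce
    if (!any(base_rows))
      stop_cogload("no baseline windows for event %d (cross event %d)", e, ce)
    b <- colMeans(fm$values[base_rows, , drop = FALSE])
    rows <- fm$meta$event == e
    V <- fm$values[rows, , drop = FALSE]
    guarded <- abs(b) < guard * scale
    den <- ifelse(guarded, 1, b)
    D <- sweep(sweep(V, 2, b), 2, den, "/")
    D[, guarded] <- 0
    out <- rbind(out, D)
    flags <- rbind(flags, matrix(guarded, nrow(D), ncol(D), byrow = TRUE))
    meta <- rbind(meta, fm$meta[rows, , drop = FALSE])
  }
  rownames(meta) <- NULL
  structure(list(values = out, meta = meta, fs = fm$fs, spec = fm$spec,
                 guard_flags = flags),
            class = "feature_matrix")
}

#' Split a task's windows into four contiguous segments
#'
#' Windows are split by count into 4 contiguous groups of near-equal size;
#' when the count is not divisible by 4 the remainder goes to the earliest
#' groups. Splitting by window count rather than wall time is equivalent at
#' a fixed hop and robust to rejected windows.
#'
#' @param n_windows Number of windows in the task (>= 4).
#' @return Integer vector of length `n_windows` with segment ids 1..4.
#' @export
segment_task <- function(n_windows) {
  if (n_windows < 4) stop_cogload("need >= 4 windows to form 4 segments, got %d",
                                  n_windows)
  sizes <- rep(n_windows %/% 4, 4)
  rem <- n_windows %% 4
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  rep(1:4, times = sizes)
}

#' Second-order features of a window group
#'
#' Per input feature, in fixed order: maximum, minimum, mean, standard
#' deviation (sample, n-1; 0 for single-window groups), median. A 3007-
#' column group therefore yields a 15035-value vector.
#'
#' @param V Windows x features matrix (non-empty).
#' @return Named numeric vector of length `5 * ncol(V)` (feature-major:
#'   all five statistics of feature 1, then feature 2, ...).
#' @export
second_order <- function(V) {
  if (is.null(dim(V))) V <- matrix(V, 1)
  if (nrow(V) == 0) stop_cogload("empty window group")
  n <- nrow(V)
  # one vectorized within-column sort gives max/min/median for all columns
  S <- matrix(V[order(col(V), V)], n)
  mx <- S[n, ]
  mn <- S[1, ]
  mu <- colMeans(V)
  sd <- if (n > 1) sqrt(pmax(colSums(V^2) - n * mu^2, 0) / (n - 1))
        else rep(0, ncol(V))
  md <- if (n %% 2 == 1) S[(n + 1) / 2, ] else (S[n / 2, ] + S[n / 2 + 1, ]) / 2
  out <- rbind(max = mx, min = mn, mean = mu, std = sd, median = md)
  nm <- colnames(V) %||% paste0("f", seq_len(ncol(V)))
  v <- as.vector(out)
  names(v) <- as.vector(outer(rownames(out), nm,
                              function(s, f) paste0(f, "__", s)))
  v
}

# build second-order rows for one block of windows split into 4 segments
segment_rows <- function(V, subject, trial, label) {
  seg <- segment_task(nrow(V))
  rows <- lapply(1:4, function(s) second_order(V[seg == s, , drop = FALSE]))
  X <- do.call(rbind, rows)
  meta <- data.frame(subject = subject, trial = trial, task = label,
                     segment = 1:4, label = label, stringsAsFactors = FALSE)
  list(x = X, meta = meta)
}

new_sample_table <- function(x, meta, scheme) {
  rownames(x) <- NULL
  rownames(meta) <- NULL
  structure(list(x = x, meta = meta, scheme = scheme),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples x %d features (%s scheme)\n",
              nrow(x$x), ncol(x$x), x$scheme))
  tb <- table(x$meta$label)
  cat("classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

# normalized per-subject feature matrices in: list of list(fm =
# baseline-normalized feature_matrix, subject = id)
cohort_feature_list <- function(cohort_features) {
  stopifnot(is.list(cohort_features), length(cohort_features) >= 1)
  cohort_features
}

#' Assemble the binary-model sample table
#'
#' One row per (subject, task, segment) where the tasks are the three code
#' tasks and the three per-trial reading controls: `subjects x 6 x 4` rows
#' (624 for a 26-subject cohort). Labels are C1, C2, C3, Control-1,
#' Control-2, Control-3.
#'
#' @param cohort_features List with one element per subject: a list with
#'   `subject` (id) and `fm` (a baseline-normalized `feature_matrix`).
#' @return A `sample_table`.
#' @export
assemble_binary <- function(cohort_features) {
  xs <- list(); ms <- list()
  for (sub in cohort_feature_list(cohort_features)) {
    fm <- sub$fm
    for (tr in sort(unique(fm$meta$trial))) {
      for (kd in c("reading", "code")) {
        rows <- fm$meta$trial == tr & fm$meta$kind == kd
        if (!any(rows))
          stop_cogload("subject %s trial %d is missing its %s task",
                       sub$subject, tr, kd)
        lab <- unique(fm$meta$label[rows])
        sr <- segment_rows(fm$values[rows, , drop = FALSE],
                           sub$subject, tr, lab)
        xs[[length(xs) + 1L]] <- sr$x
        ms[[length(ms) + 1L]] <- sr$meta
      }
    }
  }
  new_sample_table(do.call(rbind, xs), do.call(rbind, ms), "binary")
}

#' Assemble the multiclass sample table (pooled control)
#'
#' Per subject: the three code tasks each contribute 4 segments, and the
#' reading controls of all trials are pooled (concatenated in time order)
#' into a single global Control split into 4 segments: 16 rows per subject
#' (416 for 26 subjects). Labels are C1, C2, C3, Control.
#'
#' @inheritParams assemble_binary
#' @return A `sample_table`.
#' @export
assemble_multiclass <- function(cohort_features) {
  xs <- list(); ms <- list()
  for (sub in cohort_feature_list(cohort_features)) {
    fm <- sub$fm
    for (tr in sort(unique(fm$meta$trial))) {
      rows <- fm$meta$trial == tr & fm$meta$kind == "code"
      if (!any(rows))
        stop_cogload("subject %s trial %d is missing its code task",
                     sub$subject, tr)
      lab <- unique(fm$meta$label[rows])
      sr <- segment_rows(fm$values[rows, , drop = FALSE], sub$subject, tr, lab)
      xs[[length(xs) + 1L]] <- sr$x
      ms[[length(ms) + 1L]] <- sr$meta
    }
    ctl <- fm$meta$kind == "reading"
    if (!any(ctl)) stop_cogload("subject %s has no control windows", sub$subject)
    ord <- order(fm$meta$t_mid[ctl])
    V <- fm$values[ctl, , drop = FALSE][ord, , drop = FALSE]
    sr <- segment_rows(V, sub$subject, 0L, "Control")
    xs[[length(xs) + 1L]] <- sr$x
    ms[[length(ms) + 1L]] <- sr$meta
  }
  new_sample_table(do.call(rbind, xs), do.call(rbind, ms), "multiclass")
}

#' Relabel code tasks by perceived mental effort
#'
#' Merges the C2 and C3 classes into a single class "C2/C3", reflecting the
#' mental-effort saturation reported by the NASA-TLX scores between the two
#' harder code tasks; C1 and Control are unchanged. Row count and features
#' are conserved. When per-task NASA-TLX scores are supplied, the merge is
#' only applied if the cohort-mean scores of C2 and C3 differ by less than
#' `saturation_gap` (otherwise the table is returned unchanged with a
#' warning).
#'
#' @param table A `sample_table`.
#' @param tlx Optional data.frame of scores with columns `task`, `score`.
#' @param saturation_gap Maximum C2-C3 mean-score difference for merging.
#' @return The relabeled `sample_table` (scheme "nasa").
#' @export
relabel_nasa <- function(table, tlx = NULL, saturation_gap = 1) {
  stopifnot(inherits(table, "sample_table"))
  if (!is.null(tlx)) {
    m2 <- mean(tlx$score[tlx$task == "C2"])
    m3 <- mean(tlx$score[tlx$task == "C3"])
    if (is.finite(m2) && is.finite(m3) && abs(m2 - m3) >= saturation_gap) {
      warn_cogload("C2/C3 NASA-TLX means differ by %.2f >= %g; not merging",
                   abs(m2 - m3), saturation_gap)
      return(table)
    }
  }
  table$meta$label[table$meta$label %in% c("C2", "C3")] <- "C2/C3"
  table$scheme <- "nasa"
  table
}

#' Z-score scaling fitted on the training set only
#'
#' Per-feature mean and standard deviation are estimated on the training
#' table and applied to both tables, so no information from the test
#' subject leaks into the scaling. Zero-variance features scale to 0 and
#' are flagged.
#'
#' @param train,test Numeric matrices (same columns); `test` may be NULL.
#' @return List `train`, `test`, `center`, `scale`, `flags`.
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  if (nrow(train) == 0) stop_cogload("empty training table")
  ctr <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  flags <- !is.finite(sdv) | sdv < 1e-12
  sdv[flags] <- 1
  tr <- sweep(sweep(train, 2, ctr), 2, sdv, "/")
  tr[, flags] <- 0
  te <- NULL
  if (!is.null(test)) {
    te <- sweep(sweep(test, 2, ctr), 2, sdv, "/")
    te[, flags] <- 0
  }
  list(train = tr, test = te, center = ctr, scale = sdv, flags = flags)
}
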