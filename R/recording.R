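#' Construct an EEG recording object
#'
#' Container for a multichannel scalp EEG recording: a channels-by-samples
#' matrix in microvolts plus sampling rate, channel labels, scalp positions
#' and a processing history.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling frequency in Hz. Must exceed twice the highest
#'   analysis frequency (90 Hz), i.e. be at least 180 Hz.
#' @param labels Character vector of channel labels (10-10 names), one per
#'   row of `data`.
#' @param positions Optional data.frame with columns label, x, y, z; if
#'   missing, looked up from [montage_1010()]. Channels without a known
#'   position get NA coordinates and are excluded from spatial operations.
#' @param history Character vector of applied transforms.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, labels, positions = NULL,
                          history = character()) {
  if (!is.matrix(data)) data <- matrix(data, nrow = length(labels))
  storage.mode(data) <- "double"
  if (nrow(data) != length(labels))
    stop_cogload("data has %d rows but %d labels given", nrow(data), length(labels))
  if (anyNA(data)) stop_cogload("recording data contains NAs")
  if (fs < 180)
    stop_cogload("fs = %g Hz is below the 180 Hz minimum for 0-90 Hz analysis", fs)
  labels <- toupper(labels)
  if (anyDuplicated(labels)) stop_cogload("duplicate channel labels")
  if (is.null(positions)) {
    full <- montage_1010()
    positions <- data.frame(label = labels,
                            x = NA_real_, y = NA_real_, z = NA_real_,
                            stringsAsFactors = FALSE)
    hit <- match(labels, full$label)
    ok <- !is.na(hit)
    positions[ok, c("x", "y", "z")] <- full[hit[ok], c("x", "y", "z")]
  }
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 positions = positions, history = history),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (length(x$history))
    cat("history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)

rec_duration <- function(rec) ncol(rec$data) / rec$fs

add_history <- function(rec, entry) {
  rec$history <- c(rec$history, entry)
  rec
}

# index of the first sample at or after time t (1-based)
time_to_sample <- function(rec, t) as.integer(round(t * rec$fs)) + 1L

#' Extract the sample matrix of a time interval
#'
#' @param rec An `eeg_recording`.
#' @param t0,t1 Interval in seconds (half-open, relative to recording start).
#' @return Channels x samples matrix.
#' @export
crop_samples <- function(rec, t0, t1) {
  i0 <- time_to_sample(rec, t0)
  i1 <- time_to_sample(rec, t1) - 1L
  i1 <- min(i1, ncol(rec$data))
  if (i0 > i1) stop_cogload("empty interval [%g, %g)", t0, t1)
  rec$data[, i0:i1, drop = FALSE]
}
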