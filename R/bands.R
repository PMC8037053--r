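#' Canonical EEG frequency bands
#'
#' The seven analysis bands: Delta 0-4, Theta 4-8, Alpha 8-13, Beta 13-30 Hz
#' and the three gamma sub-bands LowGamma 30-50, MediumGamma 50-70,
#' HighGamma 70-90 Hz. Bands are half-open `[low, high)` so they partition
#' `[0, 90)` Hz exactly.
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("Delta", "Theta", "Alpha", "Beta",
             "LowGamma", "MediumGamma", "HighGamma"),
    low = c(0, 4, 8, 13, 30, 50, 70),
    high = c(4, 8, 13, 30, 50, 70, 90),
    stringsAsFactors = FALSE)
}

#' Sliding-window specification
#'
#' @param length Window length in seconds (default 1).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.8, i.e. 0.2 s hop).
#' @return List of class `window_spec` with `length`, `overlap`, `hop`.
#' @export
window_spec <- function(length = 1, overlap = 0.8) {
  if (length <= 0) stop_cogload("window length must be > 0")
  if (overlap < 0 || overlap >= 1) stop_cogload("overlap must be in [0, 1)")
  structure(list(length = length, overlap = overlap,
                 hop = length * (1 - overlap)),
            class = "window_spec")
}
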