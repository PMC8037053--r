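#' Idealized 10-10 scalp montage
#'
#' Returns unit-sphere coordinates for a 60-channel subset of the
#' International 10-10 system: the 64-channel quick-cap layout with the
#' mastoid (M1, M2) and cerebellar (CB1, CB2) electrodes removed.
#'
#' Positions are an idealized spherical layout computed from the 10%-arc
#' construction of the 10-10 system (18 degrees per step from the vertex),
#' not digitized cap coordinates: each coronal row (Fp, AF, F, FC, C, CP, P,
#' PO, O) sits at a fixed anterior-posterior angle from the vertex and
#' numbered electrodes are rotated laterally in 18-degree steps (odd = left,
#' even = right). This is sufficient for spherical-spline interpolation and
#' left-right pairing; it is not intended for source localization.
#'
#' @param labels Optional character vector restricting (and ordering) the
#'   returned channels. Unknown labels raise an error.
#' @return A data.frame with columns `label`, `x`, `y`, `z` (unit sphere;
#'   +x right, +y anterior, +z vertex).
#' @export
#' @examples
#' m <- montage_1010()
#' nrow(m)  # 60
montage_1010 <- function(labels = NULL) {
  rows <- list(
    FP = list(a = 72, labs = c("FP1", "FPZ", "FP2"), lat = c(-1, 0, 1)),
    AF = list(a = 54, labs = c("AF3", "AF4"), lat = c(-1, 1)),
    F  = list(a = 36, labs = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8"),
              lat = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    FC = list(a = 18, labs = c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8"),
              lat = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    C  = list(a = 0,  labs = c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8"),
              lat = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    CP = list(a = -18, labs = c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8"),
              lat = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    P  = list(a = -36, labs = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8"),
              lat = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    PO = list(a = -54, labs = c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8"),
              lat = c(-3, -2, -1, 0, 1, 2, 3)),
    O  = list(a = -72, labs = c("O1", "OZ", "O2"), lat = c(-1, 0, 1))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    a <- r$a * pi / 180
    # lateral index in 18-degree steps; Fp/AF/O rows use wider 36-degree
    # spacing so their few electrodes spread over the front/back arcs
    step <- if (length(r$labs) <= 4) 36 else 18
    l <- r$lat * step * pi / 180
    data.frame(label = r$labs,
               x = round(cos(a) * sin(l), 6),
               y = round(sin(a), 6),
               z = round(cos(a) * cos(l), 6),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  # renormalize to the unit sphere (rounding)
  nrm <- sqrt(out$x^2 + out$y^2 + out$z^2)
  out$x <- out$x / nrm; out$y <- out$y / nrm; out$z <- out$z / nrm
  if (!is.null(labels)) {
    labels <- toupper(labels)
    miss <- setdiff(labels, out$label)
    if (length(miss))
      stop_cogload("unknown 10-10 label(s): %s", paste(miss, collapse = ", "))
    out <- out[match(labels, out$label), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Default left/right electrode pairs for asymmetry features: 9 homologous
# pairs spanning frontal to occipital rows.
#' Default asymmetry electrode pairs
#'
#' Nine homologous left/right electrode pairs used for differential and
#' rational asymmetry features (9 pairs x 7 bands x 2 = 126 features, plus
#' the frontal-parietal "Brainbeat" index makes the 127 multi-channel
#' features of the standard montage).
#'
#' @return A data.frame with columns `left` and `right`.
#' @export
asymmetry_pairs_default <- function() {
  data.frame(
    left  = c("FP1", "F7", "F3", "FC3", "C3", "CP3", "P3", "P7", "O1"),
    right = c("FP2", "F8", "F4", "FC4", "C4", "CP4", "P4", "P8", "O2"),
    stringsAsFactors = FALSE
  )
}
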