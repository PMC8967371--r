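#' Canonical 62-channel electrode name list
#'
#' The standard 62-electrode montage used by 10-20-extended EEG caps
#' (the 64-lead layout minus the two mastoid references M1/M2, which are
#' reference electrodes and carry no signal). The order follows the serial
#' numbering of the electrode-topology map: prefrontal row first
#' (FP1, FPZ, FP2), then AF3/AF4, then five dense rows of nine electrodes
#' from the frontal to the parietal line, the parieto-occipital row, and
#' finally CB1, O1, OZ, O2, CB2.
#'
#' @return Character vector of 62 electrode names, in grid serial order.
#' @seealso [default_montage_62()] for the 9 x 9 grid placement.
#' @export
#' @examples
#' length(channels_62())
channels_62 <- function() {
  c("FP1", "FPZ", "FP2",
    "AF3", "AF4",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
    "CB1", "O1", "OZ", "O2", "CB2")
}

#' Frequency band definitions
#'
#' The five classical EEG rhythm bands used throughout the pipeline:
#' delta 1-4, theta 4-8, alpha 8-14, beta 14-30 and gamma 30-50 Hz.
#' Band membership of a spectral bin is half-open, `low <= f < high`,
#' with the upper edge of the last band inclusive.
#'
#' @param names character vector of band names.
#' @param low,high numeric vectors of band edges in Hz.
#' @return A data.frame with columns `name`, `low`, `high` of class
#'   `band_set`. Bands must be ascending, non-overlapping and positive.
#' @export
#' @examples
#' band_set()
band_set <- function(names = c("delta", "theta", "alpha", "beta", "gamma"),
                     low  = c(1, 4, 8, 14, 30),
                     high = c(4, 8, 14, 30, 50)) {
  stopifnot(length(names) == length(low), length(low) == length(high))
  if (any(low <= 0) || any(high <= low))
    stop("band edges must satisfy 0 < low < high")
  if (length(low) > 1 && any(low[-1] < high[-length(high)]))
    stop("bands must be non-overlapping and ascending")
  structure(data.frame(name = names, low = low, high = high,
                       stringsAsFactors = FALSE),
            class = c("band_set", "data.frame"))
}

## geometric-center frequency of each band (used by the synthetic generator)
band_centers <- function(bands) sqrt(bands$low * bands$high)
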