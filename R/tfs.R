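#' Extract per-epoch, per-channel relative band energies
#'
#' For every epoch and channel, computes a time-frequency spectrum (STFT or
#' Hilbert-Huang) and reduces it to the relative energies of the frequency
#' bands ([band_relative_energy()]). With the default 62-channel montage
#' and five bands this yields 5 x 62 = 310 features per one-second epoch.
#' The STFT path is vectorised across channels; the HHS path decomposes
#' each channel independently (EMD is nonlinear and per-signal).
#'
#' @param epochs an `eeg_epochs` object (aligned or raw).
#' @param method `"stft"` (default) or `"hhs"`.
#' @param bands a [band_set()].
#' @param window_len,overlap STFT parameters (see [stft_spectrum()]).
#' @return Object of class `tfs_matrix`: `values` (array
#'   epochs x channels x bands of shares in `[0, 1]`, each
#'   (epoch, channel) summing to 1 unless its in-range power is zero),
#'   `method`, `band_set`, `channel_names`, `meta`.
#' @export
extract_tfs <- function(epochs, method = c("stft", "hhs"),
                        bands = band_set(),
                        window_len = NULL, overlap = 0.5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  method <- match.arg(method)
  d <- dim(epochs$data)
  vals <- array(0, dim = c(d[1], d[2], nrow(bands)))
  if (method == "stft") {
    wl <- window_len %||% floor(epochs$fs / 2)
    for (ep in seq_len(d[1]))
      vals[ep, , ] <- stft_band_energy_multi(
        t(epochs$data[ep, , , drop = TRUE]), epochs$fs, bands, wl, overlap)
  } else {
    for (ep in seq_len(d[1]))
      for (ch in seq_len(d[2])) {
        dec <- emd(epochs$data[ep, ch, ])
        vals[ep, ch, ] <- band_relative_energy(
          hilbert_spectrum(dec, epochs$fs), bands)
      }
  }
  dimnames(vals) <- list(NULL, epochs$channel_names, bands$name)
  structure(list(values = vals, method = toupper(method), band_set = bands,
                 channel_names = epochs$channel_names, meta = epochs$meta),
            class = "tfs_matrix")
}

## Multichannel STFT band energies: x is samples x channels; returns
## channels x bands matrix of relative energies. Identical in value to
## stft_spectrum() + band_relative_energy() per channel (tested), but does
## one mvfft per frame for all channels.
stft_band_energy_multi <- function(x, fs, bands, window_len, overlap) {
  n <- nrow(x); nch <- ncol(x)
  if (window_len > n) stop("window longer than the signal")
  hop <- max(1L, round(window_len * (1 - overlap)))
  starts <- seq(1L, n - window_len + 1L, by = hop)
  w <- hann_window(window_len)
  K <- floor(window_len / 2) + 1L
  f <- (0:(K - 1)) * fs / window_len
  scale <- rep(1, K)
  if (K > 2) {
    dbl <- if (window_len %% 2 == 1) 2:K else 2:(K - 1L)
    scale[dbl] <- 2
  }
  acc <- matrix(0, K, nch)           # time-summed one-sided power per bin
  for (s in starts) {
    X <- stats::mvfft(x[s:(s + window_len - 1), , drop = FALSE] * w)
    acc <- acc + abs(X[1:K, , drop = FALSE])^2 * scale
  }
  acc <- acc / window_len
  nb <- nrow(bands)
  e <- matrix(0, nch, nb)
  for (b in seq_len(nb)) {
    hi_ok <- if (b == nb) f <= bands$high[b] else f < bands$high[b]
    sel <- f >= bands$low[b] & hi_ok
    e[, b] <- colSums(acc[sel, , drop = FALSE])
  }
  tot <- rowSums(e)
  pos <- tot > 0
  e[pos, ] <- e[pos, , drop = FALSE] / tot[pos]
  e
}

#' @export
print.tfs_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tfs_matrix> %s: %d epochs x %d channels x %d bands (%d features/epoch)\n",
              x$method, d[1], d[2], d[3], d[2] * d[3]))
  invisible(x)
}

#' Flatten a TFS matrix to a feature table
#'
#' One row per epoch; feature columns named `<CHANNEL>_<band>`, followed by
#' the epoch metadata columns.
#'
#' @param tfs a `tfs_matrix`.
#' @return A data.frame.
#' @export
as.data.frame.tfs_matrix <- function(x, ...) {
  d <- dim(x$values)
  m <- matrix(x$values, nrow = d[1])
  colnames(m) <- as.vector(outer(x$channel_names,
                                 x$band_set$name, paste, sep = "_"))
  cbind(as.data.frame(m), x$meta)
}
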