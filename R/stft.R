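## periodic Hann window
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Short-time Fourier power spectrum
#'
#' Squared-magnitude short-time spectrum with a Hann analysis window.
#' Defaults (window `fs / 2` samples, 50% overlap) give 2 Hz frequency
#' resolution at 200 Hz, enough to resolve the 1-4 Hz delta band inside a
#' one-second epoch. The one-sided power is normalised so that the total
#' spectrogram mass equals the summed window-weighted signal energy
#' (Parseval): interior bins are doubled and the whole spectrum divided by
#' the window length.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param window_len analysis window length in samples (default `fs / 2`).
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)`; default 0.5.
#' @return Object of class `eeg_tfd`: `power` (time-bins x frequency-bins,
#'   uV^2), `time_axis` (s, window centres), `freq_axis` (Hz),
#'   `method = "STFT"`.
#' @export
stft_spectrum <- function(x, fs, window_len = floor(fs / 2), overlap = 0.5) {
  n <- length(x)
  if (window_len > n) stop("window longer than the signal")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  stopifnot_finite(x, "signal")
  hop <- max(1L, round(window_len * (1 - overlap)))
  starts <- seq(1L, n - window_len + 1L, by = hop)
  w <- hann_window(window_len)
  frames <- vapply(starts, function(s) x[s:(s + window_len - 1)] * w,
                   numeric(window_len))
  X <- stats::mvfft(as.matrix(frames))
  K <- floor(window_len / 2) + 1L
  P <- abs(X[1:K, , drop = FALSE])^2
  if (K > 2) {
    dbl <- 2:(K - 1L)
    if (window_len %% 2 == 1) dbl <- 2:K   # odd length: no Nyquist bin
    P[dbl, ] <- 2 * P[dbl, ]
  }
  structure(list(power = t(P) / window_len,
                 time_axis = (starts - 1 + window_len / 2) / fs,
                 freq_axis = (0:(K - 1)) * fs / window_len,
                 method = "STFT"),
            class = "eeg_tfd")
}

#' @export
print.eeg_tfd <- function(x, ...) {
  cat(sprintf("<eeg_tfd> %s: %d time-bins x %d freq-bins, f in [%g, %g] Hz\n",
              x$method, nrow(x$power), ncol(x$power),
              min(x$freq_axis), max(x$freq_axis)))
  invisible(x)
}

#' Relative energy per frequency band
#'
#' Sums the time-frequency power over all time within each band
#' (half-open bins `low <= f < high`, last band inclusive of its upper
#' edge) and normalises across bands, so the shares sum to one per
#' signal. Power outside every band is excluded from numerator and
#' denominator alike. An all-zero spectrum yields all-zero shares.
#'
#' @param tfd an `eeg_tfd` from [stft_spectrum()] or [hilbert_spectrum()].
#' @param bands a [band_set()].
#' @return Named numeric vector of band shares in `[0, 1]`.
#' @export
band_relative_energy <- function(tfd, bands = band_set()) {
  stopifnot(inherits(tfd, "eeg_tfd"), inherits(bands, "band_set"))
  if (min(bands$low) >= max(tfd$freq_axis))
    stop("bands lie outside the frequency axis")
  f <- tfd$freq_axis
  tot_per_bin <- colSums(tfd$power)
  e <- vapply(seq_len(nrow(bands)), function(b) {
    hi_ok <- if (b == nrow(bands)) f <= bands$high[b] else f < bands$high[b]
    sum(tot_per_bin[f >= bands$low[b] & hi_ok])
  }, numeric(1))
  names(e) <- bands$name
  s <- sum(e)
  if (s <= 0) return(e * 0)
  e / s
}
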