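#' A single-trial multichannel EEG recording
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param channel_names ordered electrode names, one per row of `data`.
#' @param fs sampling rate in Hz.
#' @param subject_id,session_id,trial_id provenance identifiers.
#' @param label class label, or `NULL` when unlabelled.
#' @return Object of class `eeg_recording`.
#' @export
recording <- function(data, channel_names, fs, subject_id = "sub01",
                      session_id = "ses1", trial_id = "trial1",
                      label = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_names))
    stop("length(channel_names) must equal nrow(data)")
  if (fs <= 0) stop("fs must be positive")
  stopifnot_finite(data, "recording data")
  structure(list(data = data, channel_names = as.character(channel_names),
                 fs = fs, subject_id = subject_id, session_id = session_id,
                 trial_id = trial_id, label = label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s/%s: %d ch x %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, x$session_id, x$trial_id, nrow(x$data),
              ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Design a linear-phase FIR band-pass filter
#'
#' Windowed (Hamming) FIR design of even order, the standard single-pass
#' band-pass used on raw EEG: linear phase, hence no phase distortion once
#' the constant group delay of `order / 2` samples is compensated.
#' Defaults follow the pipeline's preprocessing convention: order 50,
#' pass band 1-50 Hz.
#'
#' @param low,high band edges in Hz, `0 < low < high < fs / 2`.
#' @param order filter order (number of taps minus one); must be even so
#'   the group delay is an integer number of samples.
#' @param fs sampling rate in Hz.
#' @return Object of class `fir_bandpass` with elements `coeffs`
#'   (`order + 1` symmetric taps), `order`, `low`, `high`, `fs`.
#' @export
#' @examples
#' f <- design_bandpass(1, 50, 50, fs = 200)
design_bandpass <- function(low = 1, high = 50, order = 50, fs) {
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high band edge must be below Nyquist (fs/2)")
  if (order < 2 || order %% 2 != 0)
    stop("order must be even (integer group delay)")
  h <- as.numeric(signal::fir1(order, c(low, high) / (fs / 2), type = "pass",
                               window = signal::hamming(order + 1)))
  structure(list(coeffs = h, order = order, low = low, high = high, fs = fs),
            class = "fir_bandpass")
}

#' Frequency response of an FIR filter
#'
#' @param filt a `fir_bandpass`.
#' @param freqs frequencies (Hz) at which to evaluate the transfer function.
#' @return Complex response `H(f)`; `abs()` gives the magnitude.
#' @export
filter_response <- function(filt, freqs) {
  k <- 0:filt$order
  vapply(freqs, function(f)
    sum(filt$coeffs * exp(-1i * 2 * pi * f / filt$fs * k)), complex(1))
}

#' Apply an FIR filter with group-delay compensation
#'
#' Per-channel convolution with the filter taps, centred so the output is
#' phase-aligned with the input (shift by `order / 2` samples); edges are
#' handled by reflection padding, so the output has the same length as the
#' input with no start-up transient of zeros.
#'
#' @param rec an [recording()].
#' @param filt a [design_bandpass()] result with matching `fs`.
#' @return A filtered `eeg_recording`.
#' @export
apply_filter <- function(rec, filt) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(filt, "fir_bandpass"))
  if (rec$fs != filt$fs) stop("filter was designed for a different fs")
  n <- ncol(rec$data)
  k <- filt$order
  if (n <= k) stop("signal shorter than the filter length")
  x <- t(rec$data)                                   # samples x channels
  pad <- rbind(x[(k + 1):2, , drop = FALSE],         # reflect around sample 1
               x,
               x[(n - 1):(n - k), , drop = FALSE])   # reflect around sample n
  ## centred convolution == causal filtering + shift by order/2
  y <- stats::filter(pad, filt$coeffs, method = "convolution", sides = 2)
  out <- matrix(as.numeric(y[(k + 1):(k + n), ]), nrow = n)
  rec$data <- t(out)
  rec
}

#' Resample a recording to a common rate
#'
#' Polyphase rational-ratio resampling (identity when the rate already
#' matches). Every database is brought to the common rate of 200 Hz before
#' feature extraction regardless of whether that means down- or up-sampling.
#'
#' @param rec an [recording()].
#' @param target_fs target sampling rate, Hz (default 200).
#' @return The resampled `eeg_recording`; duration preserved to within one
#'   sample.
#' @export
resample_recording <- function(rec, target_fs = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs <= 0) stop("target_fs must be positive")
  stopifnot_finite(rec$data, "recording data")
  if (target_fs == rec$fs) return(rec)
  sc <- 1
  while (sc < 1e6 &&
         (abs(rec$fs * sc - round(rec$fs * sc)) > 1e-9 ||
          abs(target_fs * sc - round(target_fs * sc)) > 1e-9)) sc <- sc * 10
  p <- round(target_fs * sc); q <- round(rec$fs * sc)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q); p <- p / d; q <- q / d
  res <- apply(rec$data, 1, function(ch) signal::resample(ch, p, q))
  rec$data <- t(res)
  rec$fs <- target_fs
  rec
}

#' Cut recordings into fixed-length epochs
#'
#' Consecutive, non-overlapping windows of `duration` seconds (default 1 s,
#' the pipeline's atomic sample); a trailing remainder shorter than one
#' epoch is discarded. Epochs inherit the trial's metadata and record their
#' index within the trial.
#'
#' @param recs a single `eeg_recording` or a list of them (all sharing
#'   `fs` and channel names).
#' @param duration epoch length in seconds.
#' @return Object of class `eeg_epochs`: list with `data` (array
#'   epochs x channels x samples), `fs`, `epoch_duration`, `channel_names`
#'   and `meta` (data.frame with subject_id, session_id, trial_id, label,
#'   epoch_in_trial).
#' @export
epoch_recordings <- function(recs, duration = 1) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  stopifnot(length(recs) >= 1)
  fs <- recs[[1]]$fs
  chans <- recs[[1]]$channel_names
  len <- round(duration * fs)
  pieces <- list(); meta <- list()
  for (r in recs) {
    if (r$fs != fs) stop("all recordings must share the sampling rate")
    if (!identical(r$channel_names, chans))
      stop("all recordings must share the channel list")
    n_ep <- floor(ncol(r$data) / len)
    if (n_ep < 1) stop("recording ", r$trial_id, " shorter than one epoch")
    idx <- seq_len(n_ep * len)
    ## channels x samples -> epochs x channels x samples
    a <- array(r$data[, idx], dim = c(length(chans), len, n_ep))
    pieces[[length(pieces) + 1L]] <- aperm(a, c(3, 1, 2))
    meta[[length(meta) + 1L]] <- data.frame(
      subject_id = r$subject_id, session_id = r$session_id,
      trial_id = r$trial_id, label = r$label %||% NA_character_,
      epoch_in_trial = seq_len(n_ep), stringsAsFactors = FALSE)
  }
  n_tot <- sum(vapply(pieces, function(p) dim(p)[1], integer(1)))
  data <- array(0, dim = c(n_tot, length(chans), len))
  at <- 0
  for (p in pieces) {
    data[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  structure(list(data = data, fs = fs, epoch_duration = duration,
                 channel_names = chans, meta = do.call(rbind, meta)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d ch x %d samples @ %g Hz; %d subject(s), %d trial(s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              length(unique(x$meta$subject_id)),
              length(unique(x$meta$trial_id))))
  invisible(x)
}

## subset an eeg_epochs by epoch index (internal)
epochs_subset <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$meta <- epochs$meta[idx, , drop = FALSE]
  rownames(epochs$meta) <- NULL
  epochs
}
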