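## Strict local extrema of a signal, plateau-tolerant: runs of equal values
## count once, using the sign pattern of the first differences.
find_extrema <- function(x) {
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  s <- sign(d[nz])
  turn <- which(s[-1] != s[-length(s)])
  idx <- nz[turn] + 1L          # last index of the extremal run
  list(max = idx[s[turn] > 0], min = idx[s[turn] < 0])
}

## Cubic-spline envelope through extrema, with up to two extrema mirrored
## across each boundary so the spline is anchored beyond the signal ends.
spline_envelope <- function(idx, val, n) {
  k <- min(2L, length(idx))
  xi <- c(2 - rev(idx[seq_len(k)]), idx, 2 * n - rev(idx)[seq_len(k)])
  yi <- c(rev(val[seq_len(k)]), val, rev(val)[seq_len(k)])
  keep <- !duplicated(xi)
  stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Standard sifting: at each step the mean of the cubic-spline upper and
#' lower envelopes (through local maxima / minima, with mirrored boundary
#' extension) is subtracted until the Huang standard-deviation criterion
#' `sum((h_prev - h)^2 / h_prev^2) < sd_thresh` is met or `max_sifts`
#' sifts have been performed; the result is one intrinsic mode function
#' (IMF). Decomposition stops when the residual has fewer than three
#' extrema or `max_imfs` IMFs have been extracted. The decomposition is
#' exactly additive: `x == rowSums(imfs) + residual` to machine precision.
#'
#' @param x numeric signal, length >= 10, finite.
#' @param max_imfs maximum number of IMFs (default 8).
#' @param max_sifts maximum sifting iterations per IMF (default 10).
#' @param sd_thresh Huang SD stopping threshold (default 0.2).
#' @return Object of class `emd_decomposition`: `imfs` (n x K matrix, one
#'   column per IMF; zero columns when the input is constant), `residual`
#'   (length-n vector), `n_imfs`.
#' @export
#' @examples
#' d <- emd(make_tone(10, 200, 1))
emd <- function(x, max_imfs = 8, max_sifts = 10, sd_thresh = 0.2) {
  n <- length(x)
  if (n < 10) stop("signal too short for EMD (need >= 10 samples)")
  stopifnot_finite(x, "signal")
  imfs <- list()
  r <- x
  eps <- .Machine$double.eps
  repeat {
    ex <- find_extrema(r)
    if (length(ex$max) + length(ex$min) < 3 || length(imfs) >= max_imfs)
      break
    h <- r
    for (s in seq_len(max_sifts)) {
      e <- find_extrema(h)
      if (length(e$max) < 2 || length(e$min) < 2) break
      m <- (spline_envelope(e$max, h[e$max], n) +
            spline_envelope(e$min, h[e$min], n)) / 2
      h_new <- h - m
      sd_crit <- sum((h - h_new)^2 / (h^2 + eps))
      h <- h_new
      if (sd_crit < sd_thresh) break
    }
    imfs[[length(imfs) + 1L]] <- h
    r <- r - h
  }
  structure(list(imfs = if (length(imfs)) do.call(cbind, imfs)
                        else matrix(0, n, 0),
                 residual = r, n_imfs = length(imfs)),
            class = "emd_decomposition")
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat(sprintf("<emd_decomposition> %d IMF(s) of length %d + residual\n",
              x$n_imfs, length(x$residual)))
  invisible(x)
}

#' Analytic signal via the Hilbert transform
#'
#' FFT construction of `z = x + i H(x)`; `Mod(z)` is the instantaneous
#' amplitude and `Arg(z)` the instantaneous phase.
#'
#' @param x numeric signal.
#' @return Complex vector of the same length.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

## phase unwrapping (add/subtract 2*pi where jumps exceed pi)
unwrap_phase <- function(p) {
  d <- diff(p)
  p + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' Instantaneous amplitude, phase and frequency of each IMF
#'
#' Per IMF: analytic signal, amplitude `A(t)`, unwrapped phase `theta(t)`,
#' and instantaneous frequency `f(t) = (1 / 2 pi) d theta / dt` by central
#' differences (one-sided at the ends).
#'
#' @param dec an [emd()] decomposition.
#' @param fs sampling rate, Hz.
#' @return List with n x K matrices `amplitude`, `phase`, `frequency`.
#' @export
instantaneous_attributes <- function(dec, fs) {
  stopifnot(inherits(dec, "emd_decomposition"))
  K <- dec$n_imfs
  n <- length(dec$residual)
  A <- P <- Fq <- matrix(0, n, K)
  for (k in seq_len(K)) {
    z <- hilbert_analytic(dec$imfs[, k])
    A[, k] <- Mod(z)
    th <- unwrap_phase(Arg(z))
    P[, k] <- th
    Fq[, k] <- c(th[2] - th[1],
                 (th[-(1:2)] - th[1:(n - 2)]) / 2,
                 th[n] - th[n - 1]) * fs / (2 * pi)
  }
  list(amplitude = A, phase = P, frequency = Fq)
}

#' Hilbert-Huang time-frequency spectrum
#'
#' Accumulates each IMF's squared instantaneous amplitude `A^2(t)` into the
#' time-frequency bin given by its instantaneous frequency at that sample.
#' Samples whose instantaneous frequency falls outside `freq_range`
#' (default 1-50 Hz) are dropped entirely, i.e. excluded from both the
#' numerator and the denominator of any later relative-energy computation.
#'
#' @param dec an [emd()] decomposition.
#' @param fs sampling rate, Hz.
#' @param freq_range frequency range retained, Hz.
#' @param n_bins number of equal-width frequency bins over `freq_range`
#'   (default 98, i.e. 0.5 Hz bins over 1-50 Hz).
#' @return Object of class `eeg_tfd` with `method = "HHS"`; `freq_axis`
#'   holds the bin centres.
#' @export
hilbert_spectrum <- function(dec, fs, freq_range = c(1, 50), n_bins = 98) {
  stopifnot(inherits(dec, "emd_decomposition"))
  n <- length(dec$residual)
  edges <- seq(freq_range[1], freq_range[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  P <- matrix(0, n, n_bins)
  if (dec$n_imfs > 0) {
    at <- instantaneous_attributes(dec, fs)
    for (k in seq_len(dec$n_imfs)) {
      f <- at$frequency[, k]
      ok <- f >= freq_range[1] & f <= freq_range[2]
      if (!any(ok)) next
      bin <- findInterval(f[ok], edges, rightmost.closed = TRUE)
      ti <- which(ok)
      a2 <- at$amplitude[ok, k]^2
      for (j in seq_along(ti)) P[ti[j], bin[j]] <- P[ti[j], bin[j]] + a2[j]
    }
  }
  structure(list(power = P, time_axis = (0:(n - 1)) / fs,
                 freq_axis = centers, method = "HHS"),
            class = "eeg_tfd")
}
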