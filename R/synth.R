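#' Single-channel test tone
#'
#' A sinusoid of given frequency and amplitude plus i.i.d. Gaussian noise,
#' the basic fixture for band-dominance checks: with `noise_sd = 0` the
#' output is exactly `amplitude * sin(2 * pi * freq * t)`.
#'
#' @param freq tone frequency in Hz; must lie strictly below the Nyquist
#'   frequency `fs / 2`.
#' @param fs sampling rate in Hz.
#' @param duration length in seconds.
#' @param amplitude peak amplitude in microvolts.
#' @param noise_sd standard deviation of additive Gaussian noise (uV).
#' @param seed optional integer seed for the noise draw.
#' @return Numeric vector of `duration * fs` samples.
#' @export
#' @examples
#' x <- make_tone(10, 200, 1)
make_tone <- function(freq, fs, duration, amplitude = 1, noise_sd = 0,
                      seed = NULL) {
  if (freq <= 0 || freq >= fs / 2)
    stop("freq must satisfy 0 < freq < fs/2 (Nyquist)")
  n <- round(duration * fs)
  x <- amplitude * sin(2 * pi * freq * (0:(n - 1)) / fs)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  x
}

#' Specification of a synthetic multi-subject EEG dataset
#'
#' Defines the study conditions the generator emulates: several subjects,
#' several emotion classes distinguished by band-power signatures, and a
#' per-subject near-identity channel-mixing matrix that shifts each
#' subject's spatial covariance (the situation Euclidean alignment is
#' designed to undo).
#'
#' Each class is characterised by oscillator amplitudes per band
#' (`class_band_profiles`); every band oscillator sits at the band's
#' geometric-centre frequency with a random phase per trial and channel,
#' and carries a fixed smooth spatial topography across channels so that
#' per-channel relative band energies genuinely differ across the scalp
#' (and are therefore perturbed by subject-specific channel mixing).
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_class trials per class per subject.
#' @param n_classes number of classes (>= 2); ignored when
#'   `class_band_profiles` is given.
#' @param fs sampling rate, Hz. Must exceed twice the highest band edge.
#' @param trial_duration trial length in seconds.
#' @param channel_names ordered electrode names; default [channels_62()].
#' @param class_band_profiles named list (one entry per class) of numeric
#'   vectors of per-band oscillation amplitudes (uV), names matching
#'   `bands$name`. Default: three classes (positive / neutral / negative)
#'   dominated by alpha, theta and beta respectively.
#' @param subject_mixing_strength magnitude (>= 0) of the random
#'   per-subject channel-mixing perturbation `A_s = I + strength * P / sqrt(C)`.
#' @param noise_sd additive Gaussian noise sd per channel (uV).
#' @param bands a [band_set()].
#' @param seed integer seed; the same seed yields bit-identical data.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects,
                       n_trials_per_class,
                       n_classes = 3,
                       fs = 200,
                       trial_duration = 12,
                       channel_names = channels_62(),
                       class_band_profiles = NULL,
                       subject_mixing_strength = 0.3,
                       noise_sd = 1,
                       bands = band_set(),
                       seed = 1) {
  if (is.null(class_band_profiles))
    class_band_profiles <- default_band_profiles(n_classes, bands)
  n_classes <- length(class_band_profiles)
  if (n_classes < 2) stop("need at least 2 classes")
  if (n_subjects < 1 || n_trials_per_class < 1)
    stop("need at least one subject and one trial per class")
  if (length(channel_names) < 1) stop("channel list must be non-empty")
  if (anyDuplicated(channel_names)) stop("duplicate channel names")
  if (fs <= 2 * max(bands$high))
    stop("fs must exceed twice the highest band edge")
  profs <- lapply(class_band_profiles, function(p) {
    if (is.null(names(p))) names(p) <- bands$name
    if (!setequal(names(p), bands$name))
      stop("profile band names must match the band set")
    p[bands$name]
  })
  if (anyDuplicated(lapply(profs, unname)))
    stop("class_band_profiles must be distinct across classes")
  if (subject_mixing_strength < 0) stop("subject_mixing_strength must be >= 0")
  structure(list(n_subjects = n_subjects,
                 n_trials_per_class = n_trials_per_class,
                 n_classes = n_classes, fs = fs,
                 trial_duration = trial_duration,
                 channel_names = channel_names,
                 class_band_profiles = profs,
                 subject_mixing_strength = subject_mixing_strength,
                 noise_sd = noise_sd, bands = bands, seed = as.integer(seed)),
            class = "synth_spec")
}

## Three-class default: alpha-dominant "positive", theta-dominant "neutral",
## beta-dominant "negative"; extra classes cycle through remaining bands.
default_band_profiles <- function(n_classes, bands) {
  base <- 0.6; dom <- 2.5
  dominant <- c("alpha", "theta", "beta", "gamma", "delta")
  labels <- c("positive", "neutral", "negative")
  out <- list()
  for (k in seq_len(n_classes)) {
    p <- rep(base, nrow(bands)); names(p) <- bands$name
    p[dominant[((k - 1) %% length(dominant)) + 1]] <- dom
    nm <- if (k <= length(labels)) labels[k] else paste0("class", k)
    out[[nm]] <- p
  }
  out
}

## Fixed per-band spatial topography (not seed-dependent): a smooth cosine
## profile over channel index, phase-shifted per band, range [0.6, 1.4].
band_topography <- function(n_channels, n_bands) {
  ch <- seq_len(n_channels) - 1
  t(vapply(seq_len(n_bands), function(b)
    1 + 0.4 * cos(2 * pi * ch / n_channels + (b - 1) * 2 * pi / n_bands),
    numeric(n_channels)))
}

#' Generate a synthetic multi-subject EEG dataset
#'
#' Draws, for every subject / class / trial, a multichannel signal that is a
#' sum of per-band sinusoids (amplitudes from the class profile times the
#' fixed band topography, random phase per trial and channel) plus white
#' Gaussian noise, then applies the subject's fixed near-identity mixing
#' matrix so that spatial covariance differs by subject. All randomness is
#' derived from `spec$seed` through per-entity sub-streams, so the output is
#' bit-identical across runs.
#'
#' @param spec a [synth_spec()].
#' @return A list of `eeg_recording` objects (one per trial) with balanced
#'   labels: `n_subjects * n_classes * n_trials_per_class` recordings.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  C <- length(spec$channel_names)
  n <- round(spec$trial_duration * spec$fs)
  tt <- (0:(n - 1)) / spec$fs
  fc <- band_centers(spec$bands)
  B <- nrow(spec$bands)
  topo <- band_topography(C, B)
  classes <- names(spec$class_band_profiles)

  mixing <- lapply(seq_len(spec$n_subjects), function(s) {
    set.seed(substream_seed(spec$seed, "mixing", s))
    diag(C) + spec$subject_mixing_strength *
      matrix(stats::rnorm(C * C), C, C) / sqrt(C)
  })

  out <- list()
  for (s in seq_len(spec$n_subjects)) {
    subj <- sprintf("sub%02d", s)
    for (ci in seq_along(classes)) {
      amp <- spec$class_band_profiles[[ci]]
      for (tr in seq_len(spec$n_trials_per_class)) {
        set.seed(substream_seed(spec$seed, "trial", s, ci, tr))
        sig <- matrix(0, C, n)
        for (b in seq_len(B)) {
          phase <- stats::runif(C, 0, 2 * pi)
          ## C x n matrix of phase-shifted sinusoids at the band centre
          sig <- sig + (amp[b] * topo[b, ]) *
            sin(outer(phase, 2 * pi * fc[b] * tt, `+`))
        }
        if (spec$noise_sd > 0)
          sig <- sig + matrix(stats::rnorm(C * n, sd = spec$noise_sd), C, n)
        out[[length(out) + 1L]] <- recording(
          data = mixing[[s]] %*% sig,
          channel_names = spec$channel_names, fs = spec$fs,
          subject_id = subj, session_id = "ses1",
          trial_id = sprintf("%s_c%d_t%02d", subj, ci, tr),
          label = classes[ci])
      }
    }
  }
  out
}

#' Write / read a synthetic dataset directory
#'
#' Standard on-disk layout consumed by the pipeline: one numeric CSV per
#' trial (channels x samples, one row per channel, no header) plus
#' `metadata.csv` with columns subject_id, session_id, trial_id, label, fs,
#' n_channels, path, and `channels.txt` with the ordered electrode names.
#'
#' @param recordings list of `eeg_recording` objects sharing channels and fs.
#' @param dir output directory (created if missing).
#' @return `write_eeg_dataset`: the directory, invisibly.
#'   `read_eeg_dataset`: a list of `eeg_recording` objects.
#' @export
write_eeg_dataset <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(seq_along(recordings), function(i) {
    r <- recordings[[i]]
    path <- sprintf("trial_%04d.csv", i)
    utils::write.table(r$data, file.path(dir, path), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    data.frame(subject_id = r$subject_id, session_id = r$session_id,
               trial_id = r$trial_id, label = r$label %||% NA_character_,
               fs = r$fs, n_channels = nrow(r$data), path = path,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  writeLines(recordings[[1]]$channel_names, file.path(dir, "channels.txt"))
  invisible(dir)
}

#' @rdname write_eeg_dataset
#' @export
read_eeg_dataset <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  chans <- readLines(file.path(dir, "channels.txt"))
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    dat <- matrix(scan(file.path(dir, m$path), sep = ",", quiet = TRUE),
                  nrow = m$n_channels, byrow = TRUE)
    recording(dat, chans, m$fs, m$subject_id, m$session_id, m$trial_id,
              label = if (is.na(m$label)) NULL else m$label)
  })
}
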