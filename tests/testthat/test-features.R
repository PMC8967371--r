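test_that("STFT locates tones, vanishes on silence and conserves energy", {
  x <- make_tone(10, 200, 1)
  tfd <- stft_spectrum(x, 200)
  expect_s3_class(tfd, "eeg_tfd")
  avg <- colMeans(tfd$power)
  expect_equal(tfd$freq_axis[which.max(avg)], 10)

  z <- stft_spectrum(rep(0, 200), 200)
  expect_true(all(z$power == 0))

  ## Parseval: total spectrogram mass == summed window-weighted energy
  set.seed(6)
  y <- rnorm(300)
  tf <- stft_spectrum(y, 200)
  w <- eegstn:::hann_window(100)
  starts <- seq(1, 201, by = 50)
  energy <- sum(vapply(starts, function(s) sum((y[s:(s + 99)] * w)^2),
                       numeric(1)))
  expect_equal(sum(tf$power), energy, tolerance = 0.01)
  expect_error(stft_spectrum(rnorm(50), 200), "window longer")
})

test_that("band shares normalise, scale-cancel and split symmetric tones", {
  tfd <- stft_spectrum(make_tone(10, 200, 1), 200)
  sh <- band_relative_energy(tfd)
  expect_equal(sum(sh), 1, tolerance = 1e-6)
  expect_identical(names(which.max(sh)), "alpha")
  expect_gt(sh["alpha"], 0.8)

  big <- band_relative_energy(stft_spectrum(9 * make_tone(10, 200, 1), 200))
  expect_equal(unname(big), unname(sh), tolerance = 1e-10)

  ## equal-power tone pair: symmetric shares once the window resolves the
  ## slow tone (a full-epoch window; at 0.5 s the 2 Hz tone leaks into the
  ## excluded DC bin and the shares skew towards beta)
  mix <- make_tone(2, 200, 2) + make_tone(20, 200, 2)
  shm <- band_relative_energy(stft_spectrum(mix, 200, window_len = 400))
  expect_equal(unname(shm["delta"]), unname(shm["beta"]), tolerance = 0.1)

  expect_equal(unname(band_relative_energy(stft_spectrum(rep(0, 200), 200))),
               rep(0, 5))
})

test_that("EMD reconstructs exactly and separates well-spaced tones", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(100:400, 1)
    x <- as.numeric(stats::filter(rnorm(n), rep(1 / 3, 3), sides = 2))
    x[is.na(x)] <- 0
    d <- emd(x)
    rec <- if (d$n_imfs) rowSums(d$imfs) + d$residual else d$residual
    expect_lt(max(abs(rec - x)) / max(1e-12, max(abs(x))), 1e-8)
  }

  tone <- make_tone(10, 200, 1)
  d <- emd(tone)
  e1 <- sum(d$imfs[, 1]^2)
  expect_gt(e1 / sum(tone^2), 0.95)

  mix <- make_tone(25, 200, 2) + make_tone(2, 200, 2)
  dm <- emd(mix)
  expect_gte(dm$n_imfs, 2)
  at <- instantaneous_attributes(dm, 200)
  mid <- 50:350
  f_per_imf <- apply(at$frequency[mid, , drop = FALSE], 2, stats::median)
  expect_equal(f_per_imf[1], 25, tolerance = 0.1)
  expect_true(any(abs(f_per_imf[-1] - 2) < 0.5))
})

test_that("EMD of a constant yields zero IMFs and the input as residual", {
  x <- rep(3.5, 64)
  d <- emd(x)
  expect_equal(d$n_imfs, 0)
  expect_equal(d$residual, x)
})

test_that("instantaneous frequency of a pure tone is recovered by HHT", {
  tone <- make_tone(10, 200, 1)
  d <- emd(tone)
  at <- instantaneous_attributes(d, 200)
  expect_lt(abs(stats::median(at$frequency[, 1]) - 10), 0.5)

  hs <- hilbert_spectrum(d, 200)
  expect_true(all(hs$power >= 0))
  sh <- band_relative_energy(hs)
  expect_identical(names(which.max(sh)), "alpha")

  ## A^2 scaling: amplitude-2 tone carries 4x the spectral mass
  hs2 <- hilbert_spectrum(emd(2 * tone), 200)
  expect_equal(sum(hs2$power) / sum(hs$power), 4, tolerance = 0.05)

  empty <- emd(rep(1, 64))
  expect_true(all(hilbert_spectrum(empty, 200)$power == 0))
})

test_that("STFT and HHS agree on the dominant band for band-centre tones", {
  bands <- band_set()
  centres <- sqrt(bands$low * bands$high)
  for (b in seq_len(nrow(bands))) {
    tone <- make_tone(centres[b], 200, 1)
    s_stft <- band_relative_energy(stft_spectrum(tone, 200), bands)
    s_hhs <- band_relative_energy(hilbert_spectrum(emd(tone), 200), bands)
    expect_identical(names(which.max(s_stft)), bands$name[b])
    expect_identical(names(which.max(s_hhs)), bands$name[b])
  }
})

test_that("extract_tfs yields 310 features per 62-channel epoch, channel-independently", {
  sp <- tiny_synth_spec(n_subjects = 1, n_trials_per_class = 1,
                        n_classes = 2, trial_duration = 1)
  ep <- epoch_recordings(generate_dataset(sp))
  tfs <- extract_tfs(ep)
  expect_equal(dim(tfs$values), c(2, 62, 5))
  expect_equal(prod(dim(tfs$values)[2:3]), 310)
  sums <- apply(tfs$values, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  ## duplicated channel -> identical feature rows
  ep2 <- ep
  ep2$data <- ep$data[, c(1, 1, 2), ]
  ep2$channel_names <- c("A", "A2", "B")
  t2 <- extract_tfs(ep2)
  expect_equal(t2$values[, 1, ], t2$values[, 2, ], tolerance = 1e-12)

  ## fast multichannel path equals the scalar reference path
  ref <- band_relative_energy(stft_spectrum(ep$data[1, 5, ], 200))
  expect_equal(unname(tfs$values[1, 5, ]), unname(ref), tolerance = 1e-10)

  ## HHS path: same contract on a couple of channels
  ep3 <- ep2
  th <- extract_tfs(ep3, method = "hhs")
  s3 <- apply(th$values, c(1, 2), sum)
  expect_true(all(abs(s3 - 1) < 1e-6 | s3 == 0))
  ref_h <- band_relative_energy(hilbert_spectrum(emd(ep3$data[1, 3, ]), 200))
  expect_equal(unname(th$values[1, 3, ]), unname(ref_h), tolerance = 1e-10)
})

test_that("feature table flattening names columns channel_band", {
  sp <- tiny_synth_spec(n_subjects = 1, n_trials_per_class = 1,
                        n_classes = 2, trial_duration = 1,
                        channel_names = c("C3", "C4"))
  tfs <- extract_tfs(epoch_recordings(generate_dataset(sp)))
  df <- as.data.frame(tfs)
  expect_true(all(c("C3_delta", "C4_gamma", "subject_id", "label")
                  %in% names(df)))
  expect_equal(df$C3_alpha, tfs$values[, "C3", "alpha"])
})
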