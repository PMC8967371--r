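test_that("band-pass design is linear phase with the specified geometry", {
  f <- design_bandpass(1, 50, 50, fs = 200)
  expect_length(f$coeffs, 51)
  expect_equal(f$coeffs, rev(f$coeffs))          # type-I symmetry
  expect_lt(abs(20 * log10(Mod(filter_response(f, 25)))), 1)   # passband
  expect_lt(20 * log10(Mod(filter_response(f, 75))), -20)      # stopband
  expect_error(design_bandpass(1, 120, 50, fs = 200), "Nyquist")
  expect_error(design_bandpass(1, 50, 51, fs = 200), "even")
})

test_that("filtering is phase-aligned and preserves in-band tones", {
  f <- design_bandpass(1, 50, 50, fs = 200)
  mk <- function(x) recording(matrix(x, 1), "CZ", 200)
  expect_equal(apply_filter(mk(rep(0, 400)), f)$data, matrix(0, 1, 400))

  tone <- make_tone(25, 200, 2)
  y <- apply_filter(mk(tone), f)$data[1, ]
  mid <- 101:300                                  # away from edge effects
  expect_lt(abs(max(abs(y[mid])) / max(abs(tone[mid])) - 1), 0.05)
  cc <- stats::ccf(y[mid], tone[mid], lag.max = 10, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0) # zero-lag peak

  ## low-frequency drift: attenuation must match the designed response
  drift <- make_tone(0.2, 200, 10)
  yd <- apply_filter(mk(drift), f)$data[1, ]
  gain2 <- mean(yd[401:1600]^2) / mean(drift[401:1600]^2)
  expect_equal(gain2, Mod(filter_response(f, 0.2))^2, tolerance = 0.05)
  expect_lt(gain2, 1)                             # attenuated, not boosted
})

test_that("filtering is linear", {
  f <- design_bandpass(1, 50, 50, fs = 200)
  set.seed(3)
  x <- matrix(rnorm(2 * 300), 2)
  y <- matrix(rnorm(2 * 300), 2)
  mk <- function(m) recording(m, c("C3", "C4"), 200)
  lhs <- apply_filter(mk(2 * x - 3 * y), f)$data
  rhs <- 2 * apply_filter(mk(x), f)$data - 3 * apply_filter(mk(y), f)$data
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("resampling preserves identity, length ratio and spectral peaks", {
  r <- recording(matrix(rnorm(200), 1), "CZ", 200)
  expect_identical(resample_recording(r, 200), r)

  r100 <- recording(matrix(rnorm(1000), 1), "CZ", 100)
  up <- resample_recording(r100, 200)
  expect_equal(ncol(up$data), 2000)
  expect_equal(up$fs, 200)

  tone <- recording(matrix(make_tone(10, 100, 10), 1), "CZ", 100)
  y <- resample_recording(tone, 200)$data[1, ]
  spec <- Mod(stats::fft(y))^2
  fr <- (seq_along(spec) - 1) / length(spec) * 200
  half <- fr < 100
  expect_equal(fr[half][which.max(spec[half])], 10, tolerance = 0.2)
})

test_that("epoching floors, slices exactly and propagates metadata", {
  x <- matrix(seq_len(2 * 2100), 2, byrow = TRUE)   # 10.5 s at 200 Hz
  r <- recording(x, c("C3", "C4"), 200, label = "positive",
                 trial_id = "t1")
  ep <- epoch_recordings(r)
  expect_equal(dim(ep$data), c(10, 2, 200))
  for (k in c(1, 5, 10))
    expect_equal(ep$data[k, 1, ], x[1, ((k - 1) * 200 + 1):(k * 200)])
  expect_true(all(ep$meta$label == "positive"))
  expect_equal(ep$meta$epoch_in_trial, 1:10)
  r$label <- "negative"
  expect_true(all(epoch_recordings(r)$meta$label == "negative"))
  expect_error(epoch_recordings(recording(matrix(0, 1, 100), "CZ", 200)),
               "shorter than one epoch")
})

test_that("epoching concatenated epoch-aligned data is the identity", {
  set.seed(8)
  x <- matrix(rnorm(3 * 600), 3)
  r <- recording(x, c("A", "B", "C"), 200)
  ep <- epoch_recordings(r)
  rebuilt <- do.call(cbind, lapply(1:3, function(k)
    matrix(ep$data[k, , ], nrow = 3)))
  expect_equal(rebuilt, x, tolerance = 1e-15)
})
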