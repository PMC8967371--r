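test_that("make_tone matches its closed form and is deterministic", {
  n <- 0:199
  expect_equal(make_tone(10, 200, 1), sin(2 * pi * 10 * n / 200))
  expect_equal(make_tone(10, 200, 1, amplitude = 0), rep(0, 200))
  expect_identical(make_tone(10, 200, 1, noise_sd = 0.1, seed = 7),
                   make_tone(10, 200, 1, noise_sd = 0.1, seed = 7))
  expect_error(make_tone(120, 200, 1), "Nyquist")
  expect_error(make_tone(100, 200, 1), "Nyquist")
})

test_that("generate_dataset yields balanced, reproducible recordings", {
  sp <- tiny_synth_spec(n_subjects = 3, n_trials_per_class = 4,
                        n_classes = 2, trial_duration = 2)
  recs <- generate_dataset(sp)
  expect_length(recs, 3 * 2 * 4)
  labs <- vapply(recs, `[[`, character(1), "label")
  expect_true(all(table(labs) == 12))
  expect_identical(recs, generate_dataset(sp))
  r <- recs[[1]]
  expect_s3_class(r, "eeg_recording")
  expect_equal(dim(r$data), c(62, 400))
  expect_identical(r$channel_names, channels_62())
})

test_that("synth_spec rejects invalid study conditions", {
  expect_error(synth_spec(1, 1, n_classes = 1), "2 classes")
  expect_error(synth_spec(0, 1), "at least one subject")
  expect_error(synth_spec(1, 1, fs = 90), "twice the highest band edge")
  prof <- list(a = c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1),
               b = c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1))
  expect_error(synth_spec(1, 1, class_band_profiles = prof), "distinct")
})

test_that("zero mixing strength shares covariance across subjects; positive strength shifts it", {
  ## high noise floor + many trials: with zero mixing only the random
  ## oscillator phases differentiate subjects' covariances, and that
  ## sampling noise shrinks with the trial count
  base <- list(n_subjects = 3, n_trials_per_class = 10, n_classes = 2,
               trial_duration = 2, seed = 21, noise_sd = 5)
  cov_dist <- function(strength) {
    sp <- do.call(synth_spec, c(base, list(
      channel_names = paste0("ch", 1:8),
      subject_mixing_strength = strength)))
    ep <- epoch_recordings(generate_dataset(sp))
    covs <- lapply(unique(ep$meta$subject_id), function(s) {
      mean_covariance(eegstn:::epochs_subset(
        ep, which(ep$meta$subject_id == s)))$mean_cov
    })
    max(vapply(seq_along(covs)[-1], function(i)
      norm(covs[[i]] - covs[[1]], "F") / norm(covs[[1]], "F"), numeric(1)))
  }
  d0 <- cov_dist(0)
  d1 <- cov_dist(0.5)
  expect_lt(d0, 0.15)      # only phase/noise sampling noise remains
  expect_gt(d1, 3 * d0)    # mixing dominates the sampling noise
})

test_that("class band profiles drive the measured relative band energies", {
  prof <- list(A = c(delta = .3, theta = .3, alpha = 3, beta = .3, gamma = .3),
               B = c(delta = .3, theta = .3, alpha = .3, beta = 3, gamma = .3))
  sp <- synth_spec(n_subjects = 2, n_trials_per_class = 3,
                   trial_duration = 2, class_band_profiles = prof,
                   subject_mixing_strength = 0, noise_sd = 0.1, seed = 4)
  tfs <- extract_tfs(epoch_recordings(generate_dataset(sp)))
  alpha_share <- apply(tfs$values[, , "alpha"], 1, mean)
  a <- tfs$meta$label == "A"
  expect_gt(mean(alpha_share[a]), mean(alpha_share[!a]))
  beta_share <- apply(tfs$values[, , "beta"], 1, mean)
  expect_gt(mean(beta_share[!a]), mean(beta_share[a]))
})

test_that("dataset directory round-trips through write/read", {
  dir <- withr::local_tempdir()
  sp <- tiny_synth_spec(n_subjects = 1, n_trials_per_class = 1,
                        trial_duration = 1,
                        channel_names = paste0("ch", 1:4))
  recs <- generate_dataset(sp)
  write_eeg_dataset(recs, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  back <- read_eeg_dataset(dir)
  expect_length(back, length(recs))
  expect_equal(back[[1]]$data, recs[[1]]$data, tolerance = 1e-12)
  expect_identical(back[[1]]$label, recs[[1]]$label)
})
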