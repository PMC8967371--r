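test_that("the learning-rate schedule matches the stepped decay", {
  expect_equal(lr_schedule(0), 0.005)
  expect_equal(lr_schedule(9), 0.005)
  expect_equal(lr_schedule(10), 0.005 * 0.95)
  expect_equal(lr_schedule(20), 0.0045125)      # 0.005 * 0.95^2
  expect_error(lr_schedule(-1), ">= 0")
  ## non-increasing, piecewise constant with 10-epoch plateaus
  lrs <- lr_schedule(0:99)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(unique(rle(lrs)$lengths), 10)
})

test_that("sequence assembly windows trials without mixing them", {
  sp <- tiny_synth_spec(n_subjects = 2, n_trials_per_class = 1,
                        n_classes = 2, trial_duration = 30, seed = 2)
  tens <- tensorize(extract_tfs(epoch_recordings(generate_dataset(sp))))
  s12 <- assemble_sequences(tens, frame_length = 12)
  expect_equal(dim(s12$x)[1:2], c(2 * 2 * 2, 12))  # floor(30/12) = 2 per trial
  ## no sequence spans two trials
  expect_equal(nrow(unique(s12$meta[c("subject_id", "trial_id")])),
               length(unique(tens$meta$trial_id)))
  s1 <- assemble_sequences(tens, frame_length = 1)
  expect_equal(dim(s1$x)[1], nrow(tens$meta))      # one sequence per epoch
  expect_error(assemble_sequences(tens, frame_length = 0), ">= 1")
  expect_error(assemble_sequences(tens, frame_length = 100), "consecutive")
})

test_that("forward pass obeys the softmax contract deterministically", {
  spec <- tiny_model_spec()
  m <- build_stn(spec, seed = 3)
  set.seed(4)
  x <- array(rnorm(4 * 3 * 9 * 9 * 5), dim = c(4, 3, 9, 9, 5))
  x[2, , , , ] <- x[1, , , , ]                     # duplicate input
  p <- predict(m, x, type = "prob")
  expect_equal(dim(p), c(4, 3))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p[1, ], p[2, ], tolerance = 1e-12)  # identical rows
  expect_identical(p, predict(m, x, type = "prob"))
  cls <- predict(m, x)
  expect_identical(cls, m$classes[max.col(p, ties.method = "first")])
  expect_error(predict(m, array(0, dim = c(1, 2, 3, 3, 5))), "dimensions")
})

test_that("parameter count is the closed-form function of the architecture", {
  spec <- stn_model_spec(n_classes = 3)
  widths <- c(5, spec$conv_widths)
  conv <- sum((9 * widths[-length(widths)] + 1) * widths[-1])
  fc1 <- (81 * 64 + 1) * 256
  lstm <- 2 * (4 * 128 * (256 + 128 + 1))
  out <- (2 * 128 + 1) * 3
  expect_equal(n_params(spec), conv + fc1 + lstm + out)
  tiny <- tiny_model_spec()
  expect_equal(n_params(tiny), n_params(build_stn(tiny)))
})

test_that("training learns a separable task, reproducibly", {
  seqs <- separable_sequences()
  spec <- tiny_model_spec()
  cfg <- stn_train_config(epochs = 30, seed = 11, batch_size = 8)
  fit <- fit_stn(seqs, spec = spec, config = cfg)
  h <- fit$history
  expect_equal(nrow(h), 30)
  expect_lt(h$loss[30], h$loss[1])
  expect_gte(max(h$accuracy), 0.9)                 # within 30 epochs
  ## bit-identical retrain under the same seed
  fit2 <- fit_stn(seqs, spec = spec, config = cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history, fit2$history)
  ## training accuracy on its own data is high
  expect_gt(mean(predict(fit, seqs) == seqs$labels), 0.9)
})

test_that("a trained model is sensitive to frame order", {
  seqs <- separable_sequences(frame_length = 6, noise = 0.3, seed = 13)
  ## add a temporal ramp so order carries information
  for (i in seq_len(dim(seqs$x)[1]))
    for (t in 1:6) seqs$x[i, t, , , ] <- seqs$x[i, t, , , ] * (0.5 + t / 6)
  fit <- fit_stn(seqs, spec = tiny_model_spec(),
                 config = stn_train_config(epochs = 15, seed = 7,
                                           batch_size = 8))
  x1 <- seqs$x[1, , , , , drop = FALSE]
  xrev <- x1[, 6:1, , , , drop = FALSE]
  p1 <- predict(fit, x1, type = "prob")
  p2 <- predict(fit, xrev, type = "prob")
  expect_gt(max(abs(p1 - p2)), 1e-4)
})

sequences_single_class <- function() {
  s <- separable_sequences(n_per_class = 4, n_classes = 3)
  keep <- s$labels == "class1"
  s$x <- s$x[keep, , , , , drop = FALSE]
  s$labels <- s$labels[keep]
  s$meta <- s$meta[keep, ]
  s
}

test_that("an untrained model on balanced data sits near chance", {
  seqs <- separable_sequences(n_per_class = 12, seed = 21)
  m <- build_stn(tiny_model_spec(), class_order = sort(unique(seqs$labels)),
                 seed = 9)
  acc <- mean(predict(m, seqs) == seqs$labels)
  expect_lt(abs(acc - 1 / 3), 0.10 + 1e-9)
  expect_error(fit_stn(sequences_single_class(), config = stn_train_config(
    epochs = 1)), "single class")
})
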