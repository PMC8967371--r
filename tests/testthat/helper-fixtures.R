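## Shared fixture builders (all data generated in code).

tiny_synth_spec <- function(n_subjects = 2, n_trials_per_class = 2,
                            trial_duration = 4, seed = 11, ...) {
  synth_spec(n_subjects = n_subjects,
             n_trials_per_class = n_trials_per_class,
             trial_duration = trial_duration, seed = seed, ...)
}

## a small architecture for fast model unit tests
tiny_model_spec <- function(n_classes = 3, input_dim = c(9, 9, 5)) {
  stn_model_spec(n_classes = n_classes, input_dim = input_dim,
                 conv_widths = c(4, 4, 4, 4, 4), embed_dim = 16,
                 lstm_hidden = 8)
}

## strongly separable sequence set built directly as arrays: class k has a
## distinct constant spatial pattern plus noise
separable_sequences <- function(n_per_class = 8, frame_length = 4,
                                n_classes = 3, dims = c(9, 9, 5),
                                noise = 0.05, seed = 5,
                                n_subjects = 2) {
  set.seed(seed)
  N <- n_per_class * n_classes
  x <- array(0, dim = c(N, frame_length, dims))
  labels <- character(N)
  subj <- character(N)
  base <- lapply(seq_len(n_classes), function(k) {
    array(stats::runif(prod(dims)), dim = dims)
  })
  i <- 0
  for (k in seq_len(n_classes)) for (r in seq_len(n_per_class)) {
    i <- i + 1
    for (t in seq_len(frame_length))
      x[i, t, , , ] <- base[[k]] + stats::rnorm(prod(dims), sd = noise)
    labels[i] <- paste0("class", k)
    subj[i] <- paste0("sub", 1 + (r - 1) %% n_subjects)
  }
  structure(list(x = x, labels = labels,
                 meta = data.frame(subject_id = subj, session_id = "ses1",
                                   trial_id = paste0("tr", seq_len(N)),
                                   label = labels, start_epoch = 1,
                                   stringsAsFactors = FALSE),
                 frame_length = as.integer(frame_length)),
            class = "stn_sequences")
}

## literal per-class F1 / weighted-F1 computation, independent of the
## implementation's table() route
brute_force_f1 <- function(y_true, y_pred, classes) {
  f1 <- support <- numeric(length(classes))
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    support[i] <- sum(y_true == k)
  }
  sum(f1 * support) / sum(support)
}

## per-scope deviation of the mean covariance from the identity
identity_deviation <- function(epochs, scope = "subject_session") {
  key <- if (scope == "subject") epochs$meta$subject_id
         else paste(epochs$meta$subject_id, epochs$meta$session_id)
  vapply(unique(key), function(k) {
    sub <- eegstn:::epochs_subset(epochs, which(key == k))
    R <- mean_covariance(sub)$mean_cov
    norm(R - diag(nrow(R)), "F") / nrow(R)
  }, numeric(1))
}
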