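#' Cross-database evaluation protocol
#'
#' Trains the full pipeline on one dataset and evaluates on a completely
#' non-overlapping second dataset. Label vocabularies are harmonised
#' first (happy to positive, sad to negative). Euclidean alignment, being
#' fully unsupervised, is computed per scope *within each dataset
#' independently* — test-side alignment uses only test-side signals, so no
#' training information leaks.
#'
#' @param train_recordings,test_recordings lists of `eeg_recording`.
#' @param config a [pipeline_config()].
#' @return An `eval_report` with `protocol = "cross_database"`, an
#'   `alignment` tag (`"with EA"` / `"without EA"`), and a `per_subject`
#'   breakdown of the test set.
#' @export
cross_database_protocol <- function(train_recordings, test_recordings,
                                    config = pipeline_config()) {
  config <- merge_config(pipeline_config(), config)
  train_recordings <- harmonize_labels(train_recordings)
  test_recordings <- harmonize_labels(test_recordings)
  tr_ids <- vapply(train_recordings, function(r)
    paste(r$subject_id, r$trial_id), character(1))
  te_ids <- vapply(test_recordings, function(r)
    paste(r$subject_id, r$trial_id), character(1))
  if (any(te_ids %in% tr_ids))
    warning("train and test sets overlap; metrics are a memorisation bound")
  tr_lab <- unique(unlist(lapply(train_recordings, `[[`, "label")))
  te_lab <- unique(unlist(lapply(test_recordings, `[[`, "label")))
  if (!all(te_lab %in% tr_lab))
    stop("test labels missing from the training vocabulary after mapping: ",
         paste(setdiff(te_lab, tr_lab), collapse = ", "))
  tr_seq <- pipeline_features(train_recordings, config)
  te_seq <- pipeline_features(test_recordings, config)
  fit <- fit_stn(tr_seq, config = pipeline_train_config(config))
  pred <- predict(fit, te_seq)
  rep <- compute_metrics(te_seq$labels, pred, class_order = fit$classes)
  rep$protocol <- "cross_database"
  rep$alignment <- if (isTRUE(config$align$enabled)) "with EA" else "without EA"
  rep$per_subject <- per_subject_breakdown(te_seq$meta$subject_id,
                                           te_seq$labels, pred)
  rep$config_hash <- config_hash(config)
  rep
}

#' Leave-one-subject-out protocol
#'
#' One fold per subject: the held-out subject's sequences are never seen
#' in training. Features (including per-subject alignment, which is
#' unsupervised and strictly per-scope) are computed once; each fold
#' refits the classifier with a fold-specific seed derived from the
#' subject identifier, so results do not depend on enumeration order.
#' Mean and standard deviation of the per-subject accuracies are reported
#' alongside the pooled confusion matrix.
#'
#' @param recordings list of labelled `eeg_recording` (>= 2 subjects).
#' @param config a [pipeline_config()].
#' @return An `eval_report` with `protocol = "loso"`, `per_subject`,
#'   `mean_accuracy` and `sd_accuracy`.
#' @export
loso_protocol <- function(recordings, config = pipeline_config()) {
  config <- merge_config(pipeline_config(), config)
  recordings <- harmonize_labels(recordings)
  seqs <- pipeline_features(recordings, config)
  subjects <- unique(seqs$meta$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects for LOSO")
  y_true <- character(0); y_pred <- character(0); fold_subj <- character(0)
  per <- list()
  for (s in subjects) {
    test_idx <- which(seqs$meta$subject_id == s)
    train_idx <- setdiff(seq_along(seqs$labels), test_idx)
    stopifnot(!any(seqs$meta$subject_id[train_idx] == s))
    if (length(unique(seqs$labels[test_idx])) < 2)
      warning("held-out subject ", s, " has a single class; fold kept")
    cfg <- pipeline_train_config(config)
    cfg$seed <- substream_seed(config$seed, "loso", s)
    fit <- fit_stn(sequences_subset(seqs, train_idx), config = cfg)
    pred <- predict(fit, sequences_subset(seqs, test_idx))
    truth <- seqs$labels[test_idx]
    m <- compute_metrics(truth, pred, class_order = fit$classes)
    per[[s]] <- data.frame(subject_id = s, accuracy = m$accuracy,
                           weighted_f1 = m$weighted_f1, n = m$n,
                           stringsAsFactors = FALSE)
    y_true <- c(y_true, truth); y_pred <- c(y_pred, pred)
    fold_subj <- c(fold_subj, rep(s, length(truth)))
  }
  rep <- compute_metrics(y_true, y_pred)
  rep$protocol <- "loso"
  rep$alignment <- if (isTRUE(config$align$enabled)) "with EA" else "without EA"
  rep$per_subject <- do.call(rbind, per)
  rownames(rep$per_subject) <- NULL
  rep$mean_accuracy <- mean(rep$per_subject$accuracy)
  rep$sd_accuracy <- stats::sd(rep$per_subject$accuracy)
  rep$config_hash <- config_hash(config)
  rep
}

#' Subject-level stratified k-fold assignment
#'
#' Partitions *subjects* (never epochs) into k folds, stratified by a
#' diagnosis or grouping label, with a seeded shuffle inside each stratum
#' before assignment. Fold sizes within a stratum differ by at most one
#' (the first `n mod k` folds take the extra subject), so for 24 + 29
#' subjects and k = 5 the fold sizes are 11, 11, 11, 11 and 9.
#'
#' @param subject_ids unique subject identifiers.
#' @param diagnosis stratification label per subject (e.g. MDD / HC);
#'   `NULL` for a single stratum.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return data.frame with columns `subject_id`, `stratum`, `fold`.
#' @export
subject_kfold <- function(subject_ids, diagnosis = NULL, k = 5, seed = 1) {
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  n <- length(subject_ids)
  if (k > n) stop("k exceeds the number of subjects")
  diagnosis <- diagnosis %||% rep("all", n)
  if (length(diagnosis) != n) stop("diagnosis must match subject_ids")
  set.seed(substream_seed(seed, "kfold"))
  out <- list()
  for (g in unique(diagnosis)) {
    ids <- subject_ids[diagnosis == g]
    if (length(ids) < k)
      warning("stratum ", g, " has fewer subjects than folds")
    ids <- sample(ids)
    sizes <- rep(length(ids) %/% k, k)
    extra <- length(ids) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    out[[g]] <- data.frame(subject_id = ids, stratum = g,
                           fold = rep(seq_len(k), times = sizes),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Frame-length sweep
#'
#' Re-assembles sequences and retrains the classifier for each candidate
#' frame length (default 8 to 32 seconds in steps of 4), evaluating with
#' the configured cross-subject holdout. Lengths exceeding every trial's
#' epoch count are skipped with a warning.
#'
#' @param recordings list of labelled `eeg_recording`.
#' @param lengths candidate frame lengths, in frames (= seconds at the
#'   default 1 s epoch).
#' @param config a [pipeline_config()].
#' @return data.frame with columns `frame_length`, `n_train`, `n_test`,
#'   `accuracy`, `weighted_f1`.
#' @export
frame_length_sweep <- function(recordings, lengths = seq(8, 32, by = 4),
                               config = pipeline_config()) {
  if (any(lengths < 1)) stop("lengths must be >= 1")
  config <- merge_config(pipeline_config(), config)
  recordings <- harmonize_labels(recordings)
  tensors <- pipeline_tensors(recordings, config)
  rows <- list()
  for (L in lengths) {
    seqs <- tryCatch(assemble_sequences(tensors, frame_length = L),
                     error = function(e) NULL)
    if (is.null(seqs)) {
      warning("frame length ", L, " exceeds every trial; skipped")
      next
    }
    sp <- holdout_split(seqs, config)
    if (!length(sp$test) || length(unique(seqs$labels[sp$train])) < 2) {
      warning("frame length ", L, ": degenerate split; skipped")
      next
    }
    fit <- fit_stn(sequences_subset(seqs, sp$train),
                   config = pipeline_train_config(config))
    pred <- predict(fit, sequences_subset(seqs, sp$test))
    m <- compute_metrics(seqs$labels[sp$test], pred,
                         class_order = fit$classes)
    rows[[length(rows) + 1L]] <- data.frame(
      frame_length = L, n_train = length(sp$train), n_test = length(sp$test),
      accuracy = m$accuracy, weighted_f1 = m$weighted_f1)
  }
  do.call(rbind, rows) %||% data.frame(frame_length = numeric(0))
}

## per-subject accuracy/F1 breakdown (internal)
per_subject_breakdown <- function(subject_ids, y_true, y_pred) {
  do.call(rbind, lapply(unique(subject_ids), function(s) {
    i <- subject_ids == s
    m <- compute_metrics(y_true[i], y_pred[i])
    data.frame(subject_id = s, accuracy = m$accuracy,
               weighted_f1 = m$weighted_f1, n = m$n,
               stringsAsFactors = FALSE)
  }))
}
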