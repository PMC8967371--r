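#' Default pipeline configuration
#'
#' Nested configuration for every stage of the pipeline. All defaults with
#' a stated convention are the pipeline's standard values: 50-order 1-50 Hz
#' FIR band-pass, common rate 200 Hz, 1 s epochs, five bands, Euclidean
#' alignment on, STFT features, 9 x 9 default montage, frame length 12,
#' batch size 32, 100 epochs, initial learning rate 0.005 decayed by 0.95
#' every 10 epochs. Override any subset by passing a nested list; unknown
#' keys are rejected.
#'
#' @param ... named overrides, e.g. `align = list(enabled = FALSE)`.
#' @return A nested list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(align = list(enabled = FALSE))
pipeline_config <- function(...) {
  base <- list(
    seed = 1L,
    synth = list(n_subjects = 4, n_trials_per_class = 4, n_classes = 3,
                 fs = 200, trial_duration = 12,
                 subject_mixing_strength = 0.3, noise_sd = 1),
    preprocess = list(low = 1, high = 50, order = 50, target_fs = 200,
                      epoch_duration = 1),
    align = list(enabled = TRUE, scope = "subject_session", shrinkage = 0),
    features = list(method = "stft"),
    spatial = list(montage_file = NULL),
    model = list(conv_widths = c(32, 64, 128, 128, 64), kernel = 3,
                 embed_dim = 256, lstm_hidden = 128),
    train = list(batch_size = 32, epochs = 100, init_lr = 0.005,
                 lr_decay = 0.95, decay_every = 10, frame_length = 12),
    eval = list(protocol = "cross_subject", test_subjects = 1))
  cfg <- merge_config(base, list(...))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' The package's CPU-scale synthetic benchmark configuration
#'
#' The default end-to-end benchmark: 4 subjects (the last held out for
#' testing), 3 classes, 4 trials per class of 12 s at 200 Hz over the
#' 62-channel montage, subject mixing strength 0.3, 1 uV noise, STFT
#' features, the default architecture, and 30 training epochs.
#'
#' @param seed global pipeline seed.
#' @param align enable Euclidean alignment (disable for the ablation arm).
#' @return A `pipeline_config`.
#' @export
benchmark_config <- function(seed = 1, align = TRUE) {
  pipeline_config(seed = as.integer(seed),
                  align = list(enabled = align),
                  train = list(epochs = 30))
}

## recursive merge with unknown-key rejection
merge_config <- function(base, override, path = "") {
  if (!length(override)) return(base)
  if (is.null(names(override)) || any(names(override) == ""))
    stop("configuration overrides must be named (at ", path, ")")
  for (k in names(override)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", paste0(path, k))
    if (is.null(override[[k]])) next    # NULL = keep the default
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
        is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(path, k, "$"))
    else
      base[[k]] <- override[[k]]
  }
  base
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML file holds any subset of the [pipeline_config()] tree; values
#' round-trip unchanged and unknown keys are rejected on read.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config`: a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path) %||% list())
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` to write.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## training config for the classifier from the pipeline tree
pipeline_train_config <- function(config) {
  stn_train_config(batch_size = config$train$batch_size,
                   epochs = config$train$epochs,
                   init_lr = config$train$init_lr,
                   lr_decay = config$train$lr_decay,
                   decay_every = config$train$decay_every,
                   seed = substream_seed(config$seed, "train"))
}

## recordings -> filtered/resampled/epoched/(aligned) -> tensors
pipeline_tensors <- function(recordings, config) {
  pp <- config$preprocess
  filts <- list()
  prepped <- lapply(recordings, function(r) {
    key <- as.character(r$fs)
    if (is.null(filts[[key]]))
      filts[[key]] <<- design_bandpass(pp$low, pp$high, pp$order, fs = r$fs)
    r <- apply_filter(r, filts[[key]])
    resample_recording(r, pp$target_fs)
  })
  epochs <- epoch_recordings(prepped, duration = pp$epoch_duration)
  if (isTRUE(config$align$enabled))
    epochs <- ea_align(epochs, scope = config$align$scope,
                       shrinkage = config$align$shrinkage)
  tfs <- extract_tfs(epochs, method = config$features$method)
  mont <- if (is.null(config$spatial$montage_file)) default_montage_62()
          else load_montage(config$spatial$montage_file)
  tensorize(tfs, mont)
}

## recordings -> sequences
pipeline_features <- function(recordings, config) {
  assemble_sequences(pipeline_tensors(recordings, config),
                     frame_length = config$train$frame_length)
}

## cross-subject holdout split on sequences
holdout_split <- function(seqs, config) {
  subs <- unique(seqs$meta$subject_id)
  ts <- config$eval$test_subjects
  test_subs <- if (is.character(ts)) ts
               else utils::tail(subs, as.integer(ts))
  test <- which(seqs$meta$subject_id %in% test_subs)
  list(train = setdiff(seq_along(seqs$labels), test), test = test)
}

#' Run the full pipeline end to end
#'
#' Executes synthesis (or loads a dataset directory), preprocessing,
#' optional Euclidean alignment, time-frequency feature extraction,
#' montage tensorisation, sequence assembly, training and evaluation
#' according to the configuration. Every stage draws its randomness from
#' sub-streams of the global seed, so reruns with the same configuration
#' are bit-identical.
#'
#' @param config a [pipeline_config()] (or named overrides via a list).
#' @param recordings optionally, a list of `eeg_recording` to use instead
#'   of synthesising data.
#' @param input_dir optionally, a dataset directory written by
#'   [write_eeg_dataset()].
#' @param verbose print stage progress and shapes.
#' @return Object of class `stn_pipeline_result`: `report` (an
#'   `eval_report`), `model` (the fitted `stn_model`), `config`,
#'   `config_hash`, `timings` (seconds per stage).
#' @export
run_pipeline <- function(config = pipeline_config(), recordings = NULL,
                         input_dir = NULL, verbose = FALSE) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[stage] <<- round(proc.time()[3] - t0, 2)
    if (verbose) message(sprintf("[%s] %.1fs", stage, timings[stage]))
    out
  }
  if (is.null(recordings)) {
    recordings <- if (!is.null(input_dir)) tick("load", {
      read_eeg_dataset(input_dir)
    }) else tick("synth", {
      sy <- config$synth
      generate_dataset(synth_spec(
        n_subjects = sy$n_subjects,
        n_trials_per_class = sy$n_trials_per_class,
        n_classes = sy$n_classes, fs = sy$fs,
        trial_duration = sy$trial_duration,
        subject_mixing_strength = sy$subject_mixing_strength,
        noise_sd = sy$noise_sd,
        seed = substream_seed(config$seed, "synth")))
    })
  }
  recordings <- harmonize_labels(recordings)
  if (config$eval$protocol == "loso") {
    report <- tick("loso", loso_protocol(recordings, config))
    out <- list(report = report, model = NULL, config = config,
                config_hash = config_hash(unclass(config)),
                timings = timings)
    class(out) <- "stn_pipeline_result"
    return(out)
  }
  seqs <- tick("features", pipeline_features(recordings, config))
  sp <- holdout_split(seqs, config)
  if (!length(sp$test) || !length(sp$train))
    stop("cross-subject split left an empty train or test set")
  fit <- tick("train", fit_stn(sequences_subset(seqs, sp$train),
                               config = pipeline_train_config(config),
                               verbose = verbose))
  report <- tick("eval", {
    pred <- predict(fit, sequences_subset(seqs, sp$test))
    m <- compute_metrics(seqs$labels[sp$test], pred,
                         class_order = fit$classes)
    m$protocol <- "cross_subject"
    m$alignment <- if (isTRUE(config$align$enabled)) "with EA"
                   else "without EA"
    m$per_subject <- per_subject_breakdown(
      seqs$meta$subject_id[sp$test], seqs$labels[sp$test], pred)
    m
  })
  out <- list(report = report, model = fit, config = config,
              config_hash = config_hash(unclass(config)), timings = timings)
  class(out) <- "stn_pipeline_result"
  out
}

#' @export
print.stn_pipeline_result <- function(x, ...) {
  cat(sprintf("<stn_pipeline_result> config %s, seed %d (%s)\n",
              x$config_hash, x$config$seed,
              x$report$alignment %||% ""))
  print(x$report)
  invisible(x)
}
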