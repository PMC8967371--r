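#' Architecture specification for the spatiotemporal classifier
#'
#' The cascaded 2D-CNN + BiLSTM: each frame (an `H x W x F` grid tensor)
#' passes through five 3 x 3 same-padded convolutions with ReLU, is
#' flattened and projected by a fully connected layer to a global spatial
#' embedding; the sequence of per-frame embeddings feeds a bidirectional
#' LSTM whose two final states are concatenated and mapped by a fully
#' connected softmax layer to class probabilities. The five-layer, 3 x 3
#' kernel structure is fixed by design; filter counts, embedding width and
#' LSTM size are configurable (the defaults suit a 9 x 9 x 5 input).
#'
#' @param n_classes number of output classes (>= 2).
#' @param input_dim integer triple `c(H, W, F)` of the input grid.
#' @param conv_widths per-layer filter counts; default `c(32, 64, 128, 128, 64)`.
#' @param kernel odd convolution kernel size; default 3.
#' @param embed_dim width of the per-frame spatial embedding; default 256.
#' @param lstm_hidden hidden units per LSTM direction; default 128.
#' @return Object of class `stn_model_spec`.
#' @export
stn_model_spec <- function(n_classes, input_dim = c(9, 9, 5),
                           conv_widths = c(32, 64, 128, 128, 64),
                           kernel = 3, embed_dim = 256, lstm_hidden = 128) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (length(input_dim) != 3 || any(input_dim < 1))
    stop("input_dim must be c(H, W, F)")
  if (kernel %% 2 != 1 || kernel < 1) stop("kernel must be odd and positive")
  if (input_dim[1] < kernel || input_dim[2] < kernel)
    stop("grid smaller than the convolution kernel")
  if (any(conv_widths < 1)) stop("conv_widths must be positive")
  structure(list(n_classes = as.integer(n_classes),
                 input_dim = as.integer(input_dim),
                 conv_widths = as.integer(conv_widths),
                 kernel = as.integer(kernel),
                 embed_dim = as.integer(embed_dim),
                 lstm_hidden = as.integer(lstm_hidden)),
            class = "stn_model_spec")
}

#' Training configuration
#'
#' Mini-batch SGD with cross-entropy loss and a stepped learning-rate
#' decay: `lr(epoch) = init_lr * lr_decay ^ floor(epoch / decay_every)`.
#' Defaults follow the pipeline's training convention: batch size 32,
#' 100 epochs, initial rate 0.005, decay 0.95 every 10 epochs, bare SGD
#' (no momentum, no weight decay).
#'
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training set.
#' @param optimizer only `"sgd"` is supported.
#' @param init_lr initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every epochs per decay step (integer floor division).
#' @param seed integer seed controlling initialisation and shuffling; the
#'   same seed reproduces training bit-for-bit.
#' @return Object of class `stn_train_config`.
#' @export
stn_train_config <- function(batch_size = 32, epochs = 100,
                             optimizer = "sgd", init_lr = 0.005,
                             lr_decay = 0.95, decay_every = 10, seed = 1) {
  if (!identical(optimizer, "sgd")) stop("only SGD is supported")
  if (batch_size < 1 || epochs < 0 || init_lr <= 0 ||
      lr_decay <= 0 || decay_every < 1)
    stop("all training configuration values must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = "sgd",
                 init_lr = init_lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 seed = as.integer(seed)),
            class = "stn_train_config")
}

#' Stepped learning-rate schedule
#'
#' `init_lr * lr_decay ^ floor(epoch / decay_every)` — piecewise constant
#' with plateaus of `decay_every` epochs; epoch counting starts at 0.
#'
#' @param epoch 0-based epoch index (>= 0).
#' @param config an [stn_train_config()].
#' @return The learning rate for that epoch.
#' @export
#' @examples
#' lr_schedule(0)    # 0.005
#' lr_schedule(20)   # 0.005 * 0.95^2
lr_schedule <- function(epoch, config = stn_train_config()) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  config$init_lr * config$lr_decay ^ (epoch %/% config$decay_every)
}

#' Assemble frame sequences from spatial tensors
#'
#' Groups epochs by trial (in within-trial order) and cuts each trial into
#' non-overlapping windows of `frame_length` consecutive frames (default
#' 12, i.e. 12 s of consecutive one-second epochs); a trailing remainder
#' shorter than one window is discarded. Frames never mix across trials;
#' each sequence inherits its trial's label.
#'
#' @param tensors a [tensorize()] result.
#' @param frame_length frames per sequence (`T`, >= 1).
#' @return Object of class `stn_sequences`: `x` (array
#'   sequences x T x H x W x F), `labels`, `meta` (subject_id, session_id,
#'   trial_id, start_epoch), `frame_length`.
#' @export
assemble_sequences <- function(tensors, frame_length = 12) {
  stopifnot(inherits(tensors, "spatial_tensor_set"))
  if (frame_length < 1) stop("frame_length must be >= 1")
  m <- tensors$meta
  d <- dim(tensors$grid)
  grp <- paste(m$subject_id, m$trial_id, sep = "\r")
  windows <- list(); meta <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    idx <- idx[order(m$epoch_in_trial[idx])]
    n_seq <- length(idx) %/% frame_length
    for (s in seq_len(n_seq)) {
      take <- idx[((s - 1) * frame_length + 1):(s * frame_length)]
      windows[[length(windows) + 1L]] <- take
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = m$subject_id[take[1]],
        session_id = m$session_id[take[1]],
        trial_id = m$trial_id[take[1]],
        label = m$label[take[1]],
        start_epoch = m$epoch_in_trial[take[1]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(windows))
    stop("no trial holds ", frame_length, " consecutive epochs")
  x <- array(0, dim = c(length(windows), frame_length, d[2], d[3], d[4]))
  for (s in seq_along(windows))
    x[s, , , , ] <- tensors$grid[windows[[s]], , , , drop = FALSE]
  meta <- do.call(rbind, meta)
  structure(list(x = x, labels = meta$label, meta = meta,
                 frame_length = as.integer(frame_length)),
            class = "stn_sequences")
}

#' @export
print.stn_sequences <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<stn_sequences> %d sequences of %d frames (%d x %d x %d grids)\n",
              d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}

## subset sequences by index (internal)
sequences_subset <- function(seqs, idx) {
  seqs$x <- seqs$x[idx, , , , , drop = FALSE]
  seqs$labels <- seqs$labels[idx]
  seqs$meta <- seqs$meta[idx, , drop = FALSE]
  rownames(seqs$meta) <- NULL
  seqs
}

#' Build an untrained spatiotemporal model
#'
#' Initialises the network parameters (He-scaled Gaussian for the
#' convolutional and fully connected weights, uniform `1/sqrt(H)` for the
#' LSTM with forget-gate bias 1) from a seed-derived stream.
#'
#' @param spec an [stn_model_spec()].
#' @param class_order class labels the softmax columns correspond to;
#'   defaults to `class1..classK`.
#' @param seed integer seed for initialisation.
#' @return Object of class `stn_model` (untrained: `trained = FALSE`).
#' @export
build_stn <- function(spec, class_order = NULL, seed = 1) {
  stopifnot(inherits(spec, "stn_model_spec"))
  classes <- class_order %||% paste0("class", seq_len(spec$n_classes))
  if (length(classes) != spec$n_classes)
    stop("class_order length must equal n_classes")
  structure(list(params = init_stn_params(spec, seed), spec = spec,
                 classes = classes, config = NULL, history = NULL,
                 trained = FALSE),
            class = "stn_model")
}

#' Fit the spatiotemporal classifier
#'
#' Seeded, shuffled mini-batch SGD with cross-entropy loss and the stepped
#' learning-rate schedule of [lr_schedule()]. Identical seeds produce
#' identical parameters and history.
#'
#' @param sequences an [assemble_sequences()] result with labels covering
#'   at least two classes.
#' @param spec an [stn_model_spec()]; by default derived from the data
#'   (grid dimensions and number of distinct labels).
#' @param config an [stn_train_config()].
#' @param model optionally, an existing `stn_model` to continue training.
#' @param verbose print per-epoch loss and accuracy.
#' @return A trained `stn_model`; `$history` is a data.frame with one row
#'   per epoch (`epoch`, `lr`, `loss`, `accuracy`).
#' @export
fit_stn <- function(sequences, spec = NULL, config = stn_train_config(),
                    model = NULL, verbose = FALSE) {
  stopifnot(inherits(sequences, "stn_sequences"),
            inherits(config, "stn_train_config"))
  d <- dim(sequences$x)
  if (any(is.na(sequences$labels)))
    stop("all training sequences must be labelled")
  classes <- sort(unique(sequences$labels))
  if (length(classes) < 2) stop("training labels cover a single class")
  if (is.null(model)) {
    if (is.null(spec))
      spec <- stn_model_spec(n_classes = length(classes),
                             input_dim = d[3:5])
    if (!all(spec$input_dim == d[3:5]))
      stop("spec input_dim does not match the sequences")
    if (spec$n_classes != length(classes))
      stop("spec n_classes does not match the labels")
    model <- build_stn(spec, class_order = classes, seed = config$seed)
  } else {
    spec <- model$spec
    if (!setequal(model$classes, classes))
      stop("model classes do not match the labels")
  }
  y <- match(sequences$labels, model$classes)
  N <- d[1]
  params <- model$params
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        loss = numeric(0), accuracy = numeric(0))
  set.seed(substream_seed(config$seed, "shuffle"))
  for (e in seq_len(config$epochs) - 1L) {
    lr <- lr_schedule(e, config)
    ord <- sample.int(N)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot_loss <- 0; correct <- 0
    for (bi in batches) {
      xb <- sequences$x[bi, , , , , drop = FALSE]
      fw <- stn_forward(params, xb, spec, want_cache = TRUE)
      tot_loss <- tot_loss + cross_entropy(fw$prob, y[bi]) * length(bi)
      correct <- correct + sum(max.col(fw$prob) == y[bi])
      grads <- stn_backward(params, fw$cache, fw$prob, y[bi])
      params <- sgd_step(params, grads, lr)
    }
    history <- rbind(history,
                     data.frame(epoch = e, lr = lr, loss = tot_loss / N,
                                accuracy = correct / N))
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  acc %.3f",
                      e, lr, tot_loss / N, correct / N))
  }
  model$params <- params
  model$config <- config
  model$history <- rbind(model$history, history)
  model$trained <- config$epochs > 0
  model
}

#' Predict class probabilities and labels
#'
#' Deterministic forward pass (the network has no stochastic layers);
#' probability rows sum to one and the predicted label is the argmax class.
#'
#' @param object an `stn_model` (trained or freshly built).
#' @param newdata an `stn_sequences` object or a numeric array
#'   `(sequences, T, H, W, F)`.
#' @param type `"class"` (default) or `"prob"`.
#' @param batch_size forward-pass chunk size (memory control only).
#' @param ... unused.
#' @return For `"class"`, a character vector; for `"prob"`, a matrix of
#'   per-class probabilities with classes as columns.
#' @export
predict.stn_model <- function(object, newdata, type = c("class", "prob"),
                              batch_size = 64, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "stn_sequences")) newdata$x else newdata
  if (length(dim(x)) != 5) stop("newdata must be a 5-d sequence array")
  if (!all(dim(x)[3:5] == object$spec$input_dim))
    stop("newdata grid dimensions do not match the model spec")
  N <- dim(x)[1]
  prob <- matrix(0, N, object$spec$n_classes,
                 dimnames = list(NULL, object$classes))
  for (at in seq(1, N, by = batch_size)) {
    bi <- at:min(at + batch_size - 1, N)
    prob[bi, ] <- stn_forward(object$params, x[bi, , , , , drop = FALSE],
                              object$spec)$prob
  }
  if (type == "prob") return(prob)
  object$classes[max.col(prob, ties.method = "first")]
}

#' @export
print.stn_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<stn_model> %s, %d classes\n",
              if (x$trained) "trained" else "untrained", s$n_classes))
  cat(sprintf("  input %d x %d x %d | conv [%s] k=%d | embed %d | BiLSTM %d/dir\n",
              s$input_dim[1], s$input_dim[2], s$input_dim[3],
              paste(s$conv_widths, collapse = ","), s$kernel,
              s$embed_dim, s$lstm_hidden))
  cat(sprintf("  parameters: %s\n",
              format(stn_param_count(x$params), big.mark = ",")))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  last epoch: loss %.4f, training accuracy %.3f\n",
                utils::tail(x$history$loss, 1),
                utils::tail(x$history$accuracy, 1)))
  invisible(x)
}

#' @export
summary.stn_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history) && nrow(object$history)) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.stn_model <- function(x, ...) {
  if (is.null(x$history) || !nrow(x$history))
    stop("model has no training history")
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", main = "training loss", ...)
  graphics::plot(h$epoch, h$accuracy, type = "l", xlab = "epoch",
                 ylab = "training accuracy", ylim = c(0, 1),
                 main = "training accuracy", ...)
  invisible(x)
}

#' Number of trainable parameters
#'
#' A pure function of the architecture specification.
#'
#' @param x an `stn_model` or `stn_model_spec`.
#' @return Integer parameter count.
#' @export
n_params <- function(x) {
  if (inherits(x, "stn_model")) return(stn_param_count(x$params))
  if (inherits(x, "stn_model_spec"))
    return(stn_param_count(init_stn_params(x, seed = 1)))
  stop("x must be an stn_model or stn_model_spec")
}
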