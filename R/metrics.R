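#' Classification metrics: accuracy, weighted F1, confusion matrix
#'
#' Accuracy is `correct / total` in percent; per-class F1 is
#' `2 P R / (P + R)` (0 when precision + recall is 0); weighted F1 is the
#' support-weighted mean of per-class F1, suited to imbalanced classes.
#' The confusion matrix has true labels on rows and predictions on
#' columns, so row sums equal per-class support.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param class_order class ordering for the confusion matrix; defaults to
#'   the sorted union of observed labels. All labels must belong to it.
#' @return Object of class `eval_report`: `accuracy` (percent),
#'   `weighted_f1` in `[0, 1]`, `confusion` (counts), `per_class`
#'   (data.frame of precision / recall / F1 / support), `n`.
#' @export
#' @examples
#' compute_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
compute_metrics <- function(y_true, y_pred, class_order = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty input")
  class_order <- class_order %||% sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% class_order))
    stop("labels outside class_order")
  ft <- factor(y_true, levels = class_order)
  fp <- factor(y_pred, levels = class_order)
  conf <- table(true = ft, predicted = fp)
  tp <- diag(conf)
  support <- rowSums(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    accuracy = 100 * sum(tp) / length(y_true),
    weighted_f1 = sum(f1 * support) / sum(support),
    confusion = unclass(conf),
    per_class = data.frame(class = class_order, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1),
                           support = as.numeric(support),
                           stringsAsFactors = FALSE),
    n = length(y_true)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report>%s accuracy %.2f%%, weighted F1 %.3f (n = %d)\n",
              if (!is.null(x$protocol)) paste0(" [", x$protocol, "]") else "",
              x$accuracy, x$weighted_f1, x$n))
  cat("confusion (true rows x predicted cols):\n")
  print(x$confusion)
  if (!is.null(x$per_subject)) {
    cat(sprintf("per-subject accuracy: mean %.2f%%, sd %.2f%%\n",
                x$mean_accuracy, x$sd_accuracy))
  }
  invisible(x)
}

#' Harmonise emotion label vocabularies
#'
#' Maps the competition-style labels happy / sad onto positive / negative
#' (neutral is shared) so that datasets with different vocabularies can be
#' pooled or used across the train/test divide.
#'
#' @param recordings list of `eeg_recording` objects.
#' @param map named character vector `from = to`.
#' @return The recordings with mapped labels.
#' @export
harmonize_labels <- function(recordings,
                             map = c(happy = "positive", sad = "negative",
                                     neutral = "neutral")) {
  lapply(recordings, function(r) {
    if (!is.null(r$label) && r$label %in% names(map))
      r$label <- unname(map[r$label])
    r
  })
}
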