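#' Cross-entropy loss
#'
#' Mean over samples of `-log p_hat` at the true class. Probabilities of
#' exactly zero at a true label are clamped to a small epsilon (with a
#' warning) rather than producing `Inf`.
#'
#' @param probs N x K matrix of predicted class probabilities (rows sum
#'   to 1)
#' @param labels integer vector of true classes in `0 .. K-1`
#' @param eps clamp for zero probabilities
#' @return scalar mean cross-entropy (nats)
#' @export
cross_entropy <- function(probs, labels, eps = 1e-12) {
  probs <- as.matrix(probs)
  K <- ncol(probs)
  labels <- as.integer(labels)
  if (length(labels) != nrow(probs)) stop("probs/labels length mismatch")
  if (any(labels < 0L | labels >= K)) stop("labels out of range 0..K-1")
  if (any(probs < 0)) stop("negative probabilities")
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  if (any(p <= 0)) {
    warning("zero probability at a true label; clamped")
    p <- pmax(p, eps)
  }
  mean(-log(p))
}

#' Confusion matrix
#'
#' @param predictions,labels equal-length integer vectors with entries in
#'   `0 .. K-1`
#' @param K number of classes
#' @return K x K integer matrix; entry `(t, p)` counts samples with true
#'   class `t` predicted as `p` (0-based classes on both axes)
#' @export
confusion_matrix <- function(predictions, labels, K) {
  predictions <- as.integer(predictions); labels <- as.integer(labels)
  if (length(predictions) != length(labels)) stop("length mismatch")
  if (any(predictions < 0L | predictions >= K) || any(labels < 0L | labels >= K))
    stop("entries out of range 0..K-1")
  cm <- matrix(0L, K, K)
  for (i in seq_along(labels))
    cm[labels[i] + 1L, predictions[i] + 1L] <- cm[labels[i] + 1L, predictions[i] + 1L] + 1L
  cm
}

#' Metrics from a confusion matrix
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (harmonic
#' mean); macro scores are unweighted class means. Classes with a zero
#' denominator score 0 and are flagged. All rates are percentages.
#'
#' @param confusion K x K matrix, rows = true class
#' @return a `metrics_report`: list with `confusion`, `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `per_class_precision`,
#'   `per_class_recall`, `per_class_f1`, `per_class_accuracy` (= recall),
#'   `zero_division` (logical per class)
#' @export
compute_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || nrow(cm) < 1L) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total == 0) stop("all-zero confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  zprec <- (tp + fp) == 0; zrec <- (tp + fn) == 0
  prec <- ifelse(zprec, 0, tp / (tp + fp))
  rec <- ifelse(zrec, 0, tp / (tp + fn))
  zf1 <- (prec + rec) == 0
  f1 <- ifelse(zf1, 0, 2 * prec * rec / (prec + rec))
  structure(list(
    confusion = cm,
    accuracy = 100 * sum(tp) / total,
    macro_precision = 100 * mean(prec),
    macro_recall = 100 * mean(rec),
    macro_f1 = 100 * mean(f1),
    per_class_precision = 100 * prec,
    per_class_recall = 100 * rec,
    per_class_f1 = 100 * f1,
    per_class_accuracy = 100 * rec,
    zero_division = zprec | zrec | zf1
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% | macro P %.2f%% R %.2f%% F1 %.2f%%\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}
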