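#' Confusion-matrix counts
#'
#' MEL is the positive class throughout the package.
#'
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(v), class = "confusion_counts")
}

#' Tally a confusion matrix from predicted and true labels
#'
#' @param predicted,truth character vectors of `"MEL"`/`"BEN"` labels.
#' @param positive the positive class (default `"MEL"`).
#' @return a [confusion_counts()] object.
#' @export
confusion_from_labels <- function(predicted, truth, positive = "MEL") {
  stopifnot(length(predicted) == length(truth))
  p <- predicted == positive; t_ <- truth == positive
  confusion_counts(tp = sum(p & t_), fp = sum(p & !t_),
                   tn = sum(!p & !t_), fn = sum(!p & t_))
}

ensure_counts <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  c
}

pct <- function(x) round_half_up(100 * x, 2)

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s has a zero denominator; defined as 0", what))
    return(0)
  }
  num / den
}

#' Confusion-matrix classification metrics
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and F1 `2TP/(2TP+FP+FN)`, each reported as a
#' percentage rounded half-up to 2 decimals. Zero denominators yield 0 with a
#' warning (accuracy with an empty total is an error).
#'
#' @param c a [confusion_counts()] object.
#' @return percentage on \[0, 100\].
#' @export
accuracy <- function(c) {
  ensure_counts(c)
  total <- c$tp + c$fp + c$tn + c$fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  pct((c$tp + c$tn) / total)
}

#' @rdname accuracy
#' @export
precision <- function(c) {
  ensure_counts(c)
  pct(safe_ratio(c$tp, c$tp + c$fp, "precision"))
}

#' @rdname accuracy
#' @export
recall <- function(c) {
  ensure_counts(c)
  pct(safe_ratio(c$tp, c$tp + c$fn, "recall"))
}

#' @rdname accuracy
#' @export
specificity <- function(c) {
  ensure_counts(c)
  pct(safe_ratio(c$tn, c$tn + c$fp, "specificity"))
}

#' @rdname accuracy
#' @export
f1_score <- function(c) {
  ensure_counts(c)
  pct(safe_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn, "F1"))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the TPR-vs-FPR sweep over all score thresholds,
#' with tied scores grouped (equivalent to the Mann-Whitney rank statistic
#' with ties averaged). MEL (the positive class) is expected to receive
#' higher scores.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary vector (1/TRUE = positive class).
#' @return AUC as a fraction in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(l, grp, sum)
  n_g <- tapply(rep(1, length(l)), grp, sum)
  tpr <- c(0, cumsum(tp_g) / np)
  fpr <- c(0, cumsum(n_g - tp_g) / nn)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Count learnable parameters of a network description
#'
#' Layer formulas: convolution
#' `(kernel_w * kernel_h * kernels_previous + 1) * kernels`; fully connected
#' `(current_neurons * previous_neurons) + current_neurons`; batch
#' normalization `2 * features` (scale and shift; running statistics are not
#' learnable). Pooling, activation, flatten and softmax layers contribute 0;
#' the two scalars of an adaptive-normalization layer count as 2.
#'
#' @param net a `network_spec`.
#' @return list with `total` and the `per_layer` integer vector.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "network_spec"))
  per <- vapply(net$layers, function(l) {
    switch(l$kind,
      conv = (l$kernel[1] * l$kernel[2] * l$in_channels + 1) * l$out_channels,
      dense = l$out_features * l$in_features + l$out_features,
      batch_norm = 2 * l$features,
      adaptive_norm = 2,
      max_pool = 0, leaky_relu = 0, flatten = 0, softmax = 0,
      stop(sprintf("unknown layer kind: %s", l$kind), call. = FALSE))
  }, numeric(1))
  list(total = sum(per), per_layer = per)
}

#' Count convolution kernels (filters) of a network description
#'
#' @param net a `network_spec`.
#' @return total number of convolution filters.
#' @export
count_kernels <- function(net) {
  stopifnot(inherits(net, "network_spec"))
  sum(vapply(net$layers, function(l)
    if (l$kind == "conv") l$out_channels else 0L, numeric(1)))
}

#' Assemble a metric report
#'
#' @param counts a [confusion_counts()] object.
#' @param scores optional positive-class scores for the AUC.
#' @param labels optional binary truth labels matching `scores`.
#' @return an object of class `metric_report`: percentages `acc, pre, rec,
#'   spe, f1`, `auc` as a fraction (NA when scores are absent), and the raw
#'   counts.
#' @export
metric_report <- function(counts, scores = NULL, labels = NULL) {
  ensure_counts(counts)
  auc <- if (!is.null(scores)) roc_auc(scores, labels) else NA_real_
  structure(list(acc = accuracy(counts), pre = precision(counts),
                 rec = recall(counts), spe = specificity(counts),
                 f1 = f1_score(counts), auc = auc,
                 tp = counts$tp, fp = counts$fp, tn = counts$tn, fn = counts$fn),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  PRE %.2f%%  REC %.2f%%  SPE %.2f%%  F1 %.2f%%",
              x$acc, x$pre, x$rec, x$spe, x$f1))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.4f", x$auc))
  cat(sprintf("\n(TP %d  FP %d  TN %d  FN %d)\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
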