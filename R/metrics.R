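#' Confusion matrix under the study's positive-class convention
#'
#' The study scores the no-IHD class as "positive" (y = 0, the normal
#' patients) and the IHD class as "negative"; the convention is carried on
#' the object so it cannot be silently inverted. Pass `positive_label = 1`
#' to flip it.
#'
#' @param truth,predicted binary label vectors of equal length.
#' @param positive_label the label counted as positive (default 0).
#' @return a `confusion_matrix` with counts `tp`, `fp`, `fn`, `tn`, the
#'   positive label, and a human-readable note on its meaning.
#' @export
confusion <- function(truth, predicted, positive_label = 0) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (length(truth) < 1L) stop("need at least one observation")
  lv <- unique(c(truth, predicted))
  if (length(lv) > 2L) stop("labels must be binary, got values: ",
                            paste(sort(lv), collapse = ", "))
  if (!positive_label %in% lv && length(lv) == 2L) {
    stop("positive_label ", positive_label, " not among observed labels")
  }
  tpos <- truth == positive_label
  ppos <- predicted == positive_label
  structure(list(
    tp = sum(ppos & tpos), fp = sum(ppos & !tpos),
    fn = sum(!ppos & tpos), tn = sum(!ppos & !tpos),
    positive_label = positive_label,
    positive_class_meaning = if (identical(as.numeric(positive_label), 0)) {
      "positive = y 0, the normal (no-IHD) patients"
    } else {
      paste("positive = label", positive_label)
    }),
    class = "confusion_matrix")
}

#' Build a confusion matrix directly from its four counts
#'
#' @param tp,fp,fn,tn nonnegative counts.
#' @inheritParams confusion
#' @return a `confusion_matrix`.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn, positive_label = 0) {
  counts <- c(tp, fp, fn, tn)
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  cm <- confusion(c(0, 1), c(0, 1), positive_label = positive_label)
  cm$tp <- tp; cm$fp <- fp; cm$fn <- fn; cm$tn <- tn
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (", x$positive_class_meaning, ")\n", sep = "")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("pred +", "pred -"), c("actual +", "actual -")))
  print(m)
  invisible(x)
}

#' Assessment metrics of a confusion matrix
#'
#' Accuracy = correctly predicted / total; TPR (sensitivity, recall) =
#' TP/(TP+FN); TNR (specificity) = TN/(FP+TN); PPV (precision) =
#' TP/(TP+FP); FPR = FP/(FP+TN); f1 = 2*recall*precision /
#' (recall+precision). A zero denominator yields `NA` and the metric's name
#' is recorded in the `undefined` attribute — never a silent zero.
#'
#' @param cm a `confusion_matrix`.
#' @return named list (`accuracy`, `tpr`, `tnr`, `ppv`, `fpr`, `f1`,
#'   `total`) with attribute `undefined`.
#' @export
metric_set <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total < 1) stop("empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tpr <- safe_div(cm$tp, cm$tp + cm$fn)
  ppv <- safe_div(cm$tp, cm$tp + cm$fp)
  out <- list(
    accuracy = (cm$tp + cm$tn) / total,
    tpr = tpr,
    tnr = safe_div(cm$tn, cm$fp + cm$tn),
    ppv = ppv,
    fpr = safe_div(cm$fp, cm$fp + cm$tn),
    f1 = f1_score(tpr, ppv),
    total = total
  )
  undef <- names(out)[vapply(out, is.na, logical(1))]
  attr(out, "undefined") <- undef
  out
}

#' f1 score from recall and precision
#'
#' @param recall,precision reals in \[0, 1\] (NA propagates).
#' @return `2 * recall * precision / (recall + precision)`, `NA` when both
#'   are zero or either is `NA`.
#' @export
f1_score <- function(recall, precision) {
  if (is.na(recall) || is.na(precision)) return(NA_real_)
  if (recall + precision == 0) return(NA_real_)
  2 * recall * precision / (recall + precision)
}

#' ROC curve by threshold sweep
#'
#' One threshold per distinct score value (ties grouped into a single
#' diagonal step), with exact (0,0) and (1,1) endpoints; predicted positive
#' means score >= threshold.
#'
#' @param scores numeric scores, larger = more positive.
#' @param truth binary labels.
#' @param positive_label label counted as positive (default 0, the study's
#'   convention).
#' @return a `roc_points` data.frame (`threshold`, `fpr`, `tpr`), FPR/TPR
#'   nondecreasing.
#' @export
roc_curve <- function(scores, truth, positive_label = 0) {
  stopifnot(length(scores) == length(truth))
  pos <- truth == positive_label
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to build a ROC curve")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, numeric(1))
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, numeric(1))
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1) {
    out <- rbind(out, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Area under a ROC curve
#'
#' Trapezoidal area; equal, by construction, to the Mann-Whitney
#' probability that a random positive scores above a random negative, with
#' ties counted one half.
#'
#' @param curve a `roc_points` data.frame from [roc_curve()].
#' @return real in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(all(c("fpr", "tpr") %in% names(curve)))
  x <- curve$fpr; y <- curve$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' AUC directly from scores and labels
#'
#' @inheritParams roc_curve
#' @return real in \[0, 1\].
#' @export
auc_scores <- function(scores, truth, positive_label = 0) {
  auc(roc_curve(scores, truth, positive_label))
}

# rank-based Mann-Whitney AUC (ties counted one half); identical to the
# trapezoid of roc_curve(), asserted by the property suite, but O(n log n)
auc_mw <- function(scores, truth, positive_label = 0) {
  pos <- truth == positive_label
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute an AUC")
  }
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percentile-bootstrap confidence interval for a test-set metric
#'
#' Resamples test rows with replacement and recomputes the metric;
#' resamples that lose a class are skipped (an error is raised if more than
#' 20\% must be skipped).
#'
#' @inheritParams roc_curve
#' @param metric `"auc"` or `"accuracy"` (accuracy thresholds scores at
#'   0.5 toward the positive class).
#' @param level confidence level in (0, 1), default 0.95.
#' @param replicates bootstrap replicates, >= 100 (default 2000).
#' @param seed RNG seed.
#' @return list with `lower`, `upper`, `point`, `level`, `n_skipped`.
#' @export
metric_ci <- function(scores, truth, metric = c("auc", "accuracy"),
                      level = 0.95, replicates = 2000L, seed = 1L,
                      positive_label = 0) {
  metric <- match.arg(metric)
  stopifnot(level > 0, level < 1, replicates >= 100)
  n <- length(truth)
  negative_label <- if (identical(as.numeric(positive_label), 0)) 1 else 0
  eval_metric <- function(s, t) {
    if (metric == "auc") {
      auc_mw(s, t, positive_label)
    } else {
      pred <- ifelse(s >= 0.5, positive_label, negative_label)
      metric_set(confusion(t, pred, positive_label))$accuracy
    }
  }
  point <- eval_metric(scores, truth)
  set.seed(seed)
  vals <- numeric(0)
  skipped <- 0L
  for (b in seq_len(replicates)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(truth[idx])) < 2L && metric == "auc") {
      skipped <- skipped + 1L
      next
    }
    vals <- c(vals, eval_metric(scores[idx], truth[idx]))
  }
  if (skipped > 0.2 * replicates) {
    stop("more than 20% of bootstrap resamples were single-class; ",
         "the test set is too small or too imbalanced for this interval")
  }
  qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lower = max(0, qs[1]), upper = min(1, qs[2]), point = point,
       level = level, n_skipped = skipped)
}

#' Export ROC points as CSV
#'
#' @param curve a `roc_points` data.frame.
#' @param path output CSV path.
#' @export
write_roc <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
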