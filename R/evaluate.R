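# Confusion-derived metrics, ROC/AUROC, operating-point selection, and
# seed-aggregated confidence intervals.

#' Confusion-matrix metrics at a threshold
#'
#' Thresholds probabilities at `threshold` (predicted positive when
#' `prob >= threshold`) and reports precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2*precision*recall/(precision+recall), and
#' FPR = FP/(FP+TN). Zero-denominator conventions: precision 0 when no
#' positive predictions, recall 0 when no positive labels, F1 0 when
#' precision + recall = 0, FPR 0 when no negative labels.
#'
#' @param labels Binary labels (0/1).
#' @param probs Scores/probabilities in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return List with the four metrics, the threshold, and the counts
#'   (`tp`, `fp`, `tn`, `fn`).
#' @export
confusion_metrics <- function(labels, probs, threshold = 0.5) {
  if (length(labels) != length(probs))
    abort_invalid("labels and probs must have equal length",
                  class = "weakeeg_invalid_input")
  pred <- probs >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
  list(precision = precision, recall = recall, f1 = f1, fpr = fpr,
       threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve and AUROC
#'
#' Enumerates the ROC curve at every distinct score and computes the AUROC
#' as the probability that a random positive outscores a random negative,
#' with ties counting one half (the rank/Mann-Whitney estimator).
#'
#' @param labels Binary labels; both classes must be present.
#' @param probs Scores.
#' @return List with `roc` (data frame: threshold, fpr, tpr, anchored at
#'   (0,0) and (1,1)) and `auroc`.
#' @export
roc_auroc <- function(labels, probs) {
  if (length(labels) != length(probs))
    abort_invalid("labels and probs must have equal length",
                  class = "weakeeg_invalid_input")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    abort_invalid("AUROC undefined with a single class",
                  class = "weakeeg_undefined_metric")
  r <- rank(probs)
  auroc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(probs), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(probs >= t & labels == 1) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(probs >= t & labels == 0) / nn, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  list(roc = roc, auroc = auroc)
}

#' Choose an operating point on a ROC curve
#'
#' With `target_tpr`, returns the largest threshold whose TPR meets the
#' target (ties broken toward lower FPR); with `target_fpr`, the smallest
#' threshold whose FPR stays within the target (ties toward higher TPR).
#' Clinically, e.g., the threshold achieving a 90% true-positive rate.
#'
#' @param roc ROC data frame from [roc_auroc()].
#' @param target_tpr,target_fpr Exactly one must be given.
#' @return List with `threshold`, `tpr`, `fpr`.
#' @export
operating_point <- function(roc, target_tpr = NULL, target_fpr = NULL) {
  if (is.null(roc) || nrow(roc) == 0) abort_invalid("empty ROC curve")
  if (is.null(target_tpr) == is.null(target_fpr))
    abort_invalid("give exactly one of target_tpr or target_fpr")
  if (!is.null(target_tpr)) {
    ok <- roc$tpr >= target_tpr
    if (!any(ok))
      abort_invalid("no threshold achieves the target TPR",
                    class = "weakeeg_no_feasible_threshold")
    cand <- roc[ok, ]
    cand <- cand[cand$fpr == min(cand$fpr), ]
    best <- cand[which.max(cand$threshold), ]
  } else {
    ok <- roc$fpr <= target_fpr
    if (!any(ok))
      abort_invalid("no threshold achieves the target FPR",
                    class = "weakeeg_no_feasible_threshold")
    cand <- roc[ok, ]
    cand <- cand[cand$tpr == max(cand$tpr), ]
    best <- cand[which.min(cand$threshold), ]
  }
  list(threshold = best$threshold, tpr = best$tpr, fpr = best$fpr)
}

#' Aggregate a metric over training seeds
#'
#' Mean, Student-t 95% confidence interval, and median over per-seed values
#' (the convention used for error bars over five training runs).
#'
#' @param values Numeric vector of per-seed metric values (length >= 2).
#' @param conf Confidence level (default 0.95).
#' @return List with `mean`, `ci` (length-2), `median`, `n`.
#' @export
aggregate_over_seeds <- function(values, conf = 0.95) {
  if (length(values) < 2)
    abort_invalid("need at least 2 replicate values",
                  class = "weakeeg_insufficient_replicates")
  n <- length(values)
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  list(mean = m, ci = c(m - tq * se, m + tq * se),
       median = stats::median(values), n = n)
}

#' Pointwise-median ROC curve over seeds
#'
#' Interpolates each replicate ROC (as a step function, taking the maximal
#' TPR attained at or below each FPR) onto a common grid of 101 evenly
#' spaced FPR points and reports the pointwise median TPR.
#'
#' @param rocs List of ROC data frames from [roc_auroc()].
#' @param grid_size Number of FPR grid points (default 101).
#' @return Data frame with `fpr` and `tpr` (median).
#' @export
median_roc <- function(rocs, grid_size = 101L) {
  grid <- seq(0, 1, length.out = grid_size)
  tprs <- vapply(rocs, function(rc) {
    o <- order(rc$fpr, rc$tpr)
    f <- rc$fpr[o]; t <- cummax(rc$tpr[o])
    vapply(grid, function(g) max(0, t[f <= g]), numeric(1))
  }, numeric(grid_size))
  data.frame(fpr = grid, tpr = apply(tprs, 1, stats::median))
}

#' Full evaluation report for a set of scored clips
#'
#' @param labels Binary labels.
#' @param probs Scores.
#' @param threshold Threshold for the confusion-derived part (default 0.5).
#' @return List combining [confusion_metrics()] and [roc_auroc()].
#' @export
metrics_report <- function(labels, probs, threshold = 0.5) {
  cm <- confusion_metrics(labels, probs, threshold)
  ra <- roc_auroc(labels, probs)
  c(cm, list(auroc = ra$auroc, roc = ra$roc))
}
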