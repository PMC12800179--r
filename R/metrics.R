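# Evaluation suite: confusion counts and scalar metrics, ROC/AUC, PR/AP,
# calibration curves, probability summaries and the Wilcoxon signed-rank
# model comparison. The positive class throughout is "manipulated".

#' Confusion counts and scalar metrics
#'
#' Counts with `"manipulated"` as the positive class: `true_real`
#' (correctly kept real), `true_manip` (correctly flagged), `false_pos`
#' (real flagged as manipulated), `false_neg` (manipulation missed).
#' Accuracy, precision, recall and F1 follow; ratios with a zero
#' denominator are returned as `NA` (undefined), never as 0.
#'
#' @param labels,predictions equal-length vectors with values `"real"` /
#'   `"manipulated"`.
#' @return list of class `confusion_metrics` with the four counts and the
#'   scalar metrics.
#' @export
confusion_and_metrics <- function(labels, predictions) {
  if (length(labels) == 0) stop_param("empty input")
  if (length(labels) != length(predictions))
    stop_param("labels and predictions must have equal length")
  labels <- as_label(labels); predictions <- as_label(predictions)
  tp <- sum(labels == "manipulated" & predictions == "manipulated")
  tn <- sum(labels == "real" & predictions == "real")
  fp <- sum(labels == "real" & predictions == "manipulated")
  fn <- sum(labels == "manipulated" & predictions == "real")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(true_real = tn, true_manip = tp,
                 false_pos = fp, false_neg = fn,
                 accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall, f1 = f1),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(paste0("<confusion_metrics> TN=%d TP=%d FP=%d FN=%d\n",
                     "  accuracy %.3f  precision %s  recall %s  F1 %s\n"),
              x$true_real, x$true_manip, x$false_pos, x$false_neg,
              x$accuracy, format(x$precision, digits = 3),
              format(x$recall, digits = 3), format(x$f1, digits = 3)))
  invisible(x)
}

score_prep <- function(labels, scores) {
  labels <- as_label(labels)
  if (length(labels) != length(scores)) stop_param("length mismatch")
  if (any(scores < -1e-12 | scores > 1 + 1e-12))
    stop_param("scores must lie in [0, 1]")
  list(pos = labels == "manipulated", scores = as.numeric(scores))
}

#' ROC curve and AUC
#'
#' AUC equals the probability that a random positive outscores a random
#' negative, with tied scores contributing one half (computed via
#' midranks, equivalent to trapezoidal integration of the ROC curve over
#' all thresholds). Returns `NA` when either class is absent.
#'
#' @param labels `"real"` / `"manipulated"` vector.
#' @param scores predicted probabilities of `"manipulated"` in `[0, 1]`.
#' @return list with `auc` and `roc` (data frame of `threshold`, `fpr`,
#'   `tpr` at each distinct score, descending).
#' @export
roc_auc <- function(labels, scores) {
  sp <- score_prep(labels, scores)
  np <- sum(sp$pos); nn <- sum(!sp$pos)
  if (np == 0 || nn == 0)
    return(list(auc = NA_real_, roc = NULL))
  r <- rank(sp$scores)  # midranks
  auc <- (sum(r[sp$pos]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(sp$scores), decreasing = TRUE)
  roc <- data.frame(threshold = thr,
                    fpr = vapply(thr, function(t) sum(sp$scores[!sp$pos] >= t) / nn, 0),
                    tpr = vapply(thr, function(t) sum(sp$scores[sp$pos] >= t) / np, 0))
  list(auc = auc, roc = roc)
}

#' Precision-recall curve and average precision
#'
#' Precision and recall are evaluated at every distinct score threshold
#' (descending); average precision is the step-interpolated sum
#' `AP = sum_i (R_i - R_{i-1}) * P_i`. Rank-based: invariant to monotone
#' transformations of the scores. Returns `NA` when either class is
#' absent.
#'
#' @inheritParams roc_auc
#' @return list with `ap` and `pr` (data frame `threshold`, `recall`,
#'   `precision`).
#' @export
pr_curve <- function(labels, scores) {
  sp <- score_prep(labels, scores)
  np <- sum(sp$pos); nn <- sum(!sp$pos)
  if (np == 0 || nn == 0) return(list(ap = NA_real_, pr = NULL))
  thr <- sort(unique(sp$scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(sp$scores[sp$pos] >= t), 0)
  fp <- vapply(thr, function(t) sum(sp$scores[!sp$pos] >= t), 0)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rec <- tp / np
  ap <- sum(diff(c(0, rec)) * prec, na.rm = TRUE)
  list(ap = ap,
       pr = data.frame(threshold = thr, recall = rec, precision = prec))
}

#' Calibration (reliability) curve
#'
#' Equal-width probability bins on `[0, 1]`; for each nonempty bin the
#' mean predicted probability, the empirical fraction of positives and
#' the bin count are reported (empty bins are omitted). A score of
#' exactly 1 falls into the last bin.
#'
#' @inheritParams roc_auc
#' @param n_bins number of bins (`>= 1`).
#' @return data frame with `bin`, `mean_score`, `fraction_positive`,
#'   `count`; the counts sum to `length(labels)`.
#' @export
calibration_curve <- function(labels, scores, n_bins = 10L) {
  if (n_bins < 1) stop_param("n_bins must be >= 1")
  sp <- score_prep(labels, scores)
  bin <- pmin(floor(sp$scores * n_bins) + 1L, n_bins)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(bin = b, mean_score = mean(sp$scores[i]),
               fraction_positive = mean(sp$pos[i]), count = sum(i))
  }))
  rownames(out) <- NULL
  out
}

#' Median and interquartile range of predicted probabilities
#'
#' Quantiles use the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param scores nonempty numeric vector.
#' @return list with `median`, `q25`, `q75`.
#' @export
probability_summary <- function(scores) {
  if (length(scores) == 0) stop_param("empty input")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q25 = q[1], q75 = q[3])
}

#' Wilcoxon signed-rank test for paired model comparison
#'
#' Two-sided paired test on per-seed metric differences. Pairs with an
#' undefined metric (`NA`) and zero differences are dropped; absolute differences are ranked with midrank ties;
#' `W = min(W+, W-)`. The p-value is exact (full enumeration of the `2^n`
#' sign assignments, valid with ties) for `n <= exact_max`, otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. If every difference is zero the statistic is undefined (`NA`)
#' and `p = 1` by convention.
#'
#' @param a,b equal-length paired metric series (e.g. one value per seed).
#' @param exact_max largest `n` for which the exact enumeration is used.
#' @return list with `statistic` (W), `p_value` and `n` (nonzero pairs).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 12L) {
  if (length(a) != length(b)) stop_param("series must be paired")
  keep <- is.finite(a) & is.finite(b)  # pairs with undefined metrics drop
  d <- a[keep] - b[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, p_value = 1, n = 0L))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0]); w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  if (n <= exact_max) {
    # enumerate all sign assignments of the rank vector
    count <- 0L
    total <- 2^n
    for (m in 0:(total - 1)) {
      signs <- bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0
      wp <- sum(r[signs])
      if (min(wp, sum(r) - wp) <= w + 1e-9) count <- count + 1L
    }
    p <- count / total
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu + 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(z))
  }
  list(statistic = w, p_value = p, n = n)
}

#' Full evaluation report for one model on one test set
#'
#' Bundles every quantitative analysis of the evaluation suite for a
#' score vector: confusion counts and scalar metrics at the given
#' threshold, ROC/AUC, PR/AP, the calibration table and the probability
#' summary.
#'
#' @param labels true labels.
#' @param scores predicted probabilities of `"manipulated"`.
#' @param threshold decision threshold (scores `>=` threshold are called
#'   manipulated).
#' @param n_bins calibration bins.
#' @return list of class `evaluation_report`.
#' @export
evaluation_report <- function(labels, scores, threshold = 0.5, n_bins = 10L) {
  pred <- ifelse(scores >= threshold, "manipulated", "real")
  cm <- confusion_and_metrics(labels, pred)
  roc <- roc_auc(labels, scores)
  pr <- pr_curve(labels, scores)
  structure(list(confusion = cm, auc = roc$auc, roc = roc$roc,
                 ap = pr$ap, pr = pr$pr,
                 calibration = calibration_curve(labels, scores, n_bins),
                 probability = probability_summary(scores),
                 threshold = threshold, n = length(labels)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> n=%d  accuracy %.3f  AUC %s  AP %s\n",
                     "  median p %.3f (IQR %.3f-%.3f)\n"),
              x$n, x$confusion$accuracy, format(x$auc, digits = 3),
              format(x$ap, digits = 3), x$probability$median,
              x$probability$q25, x$probability$q75))
  invisible(x)
}

#' Plot an evaluation report
#'
#' Draws the ROC curve, the precision-recall curve and the reliability
#' diagram side by side.
#'
#' @param x an [evaluation_report()].
#' @param ... ignored.
#' @export
plot.evaluation_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  plot(c(0, x$roc$fpr, 1), c(0, x$roc$tpr, 1), type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC %.3f)", x$auc))
  graphics::abline(0, 1, lty = 3)
  plot(x$pr$recall, x$pr$precision, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Recall", ylab = "Precision", main = sprintf("PR (AP %.3f)", x$ap))
  plot(x$calibration$mean_score, x$calibration$fraction_positive,
       type = "b", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Mean predicted probability", ylab = "Fraction positive",
       main = "Calibration")
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
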