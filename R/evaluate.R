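# Classification metrics: confusion counts at the 0.5 decision threshold,
# ACC / PRE / recall / F-value / MCC, and the ROC and precision-recall
# curves with their areas.

#' Confusion-matrix counts at a decision threshold
#'
#' A molecule is called active iff its score is strictly greater than the
#' threshold (a score of exactly 0.5 is inactive under the default).
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Binary 0/1 labels, same length.
#' @param threshold Decision threshold, default 0.5.
#' @return List of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length: ",
         length(scores), " vs ", length(labels))
  }
  stopifnot(all(labels %in% c(0, 1)))
  pred <- scores > threshold
  structure(list(
    TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
    FN = sum(!pred & labels == 1), TN = sum(!pred & labels == 0)
  ), class = "confusion_counts")
}

#' Confusion-matrix metrics
#'
#' ACC = (TP+TN)/N, PRE = TP/(TP+FP), recall = TP/(TP+FN),
#' F-value = 2TP/(2TP+FP+FN), and the Matthews correlation coefficient
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as 0 and listed in the
#' `degenerate` attribute instead of raising, so evaluation survives
#' degenerate predictions.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named list `acc`, `pre`, `recall`, `f_value`, `mcc`, with
#'   attribute `degenerate` naming zero-denominator metrics.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  total <- tp + fp + fn + tn
  if (total == 0) stop("no items to evaluate")
  degen <- character(0)
  safe <- function(num, den, nm) {
    if (den == 0) { degen <<- c(degen, nm); 0 } else num / den
  }
  acc <- (tp + tn) / total
  pre <- safe(tp, tp + fp, "pre")
  recall <- safe(tp, tp + fn, "recall")
  f_value <- safe(2 * tp, 2 * tp + fp + fn, "f_value")
  mden <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (mden == 0) { degen <- c(degen, "mcc"); 0 } else
    (tp * tn - fn * fp) / mden
  structure(list(acc = acc, pre = pre, recall = recall,
                 f_value = f_value, mcc = mcc),
            degenerate = degen)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of TPR against FPR over all score thresholds,
#' equivalent to the pair-counting estimator P(score+ > score-) + 0.5
#' P(tie).
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @param curve If `TRUE` also return the (FPR, TPR) points.
#' @return The AUROC, or (with `curve`) a list `auc`, `points`.
#' @export
auroc <- function(scores, labels, curve = FALSE) {
  ro <- roc_points(scores, labels)
  auc <- sum(diff(ro$fpr) * (utils::head(ro$tpr, -1) + utils::tail(ro$tpr, -1)) / 2)
  if (curve) list(auc = auc, points = ro) else auc
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: sum over distinct thresholds of precision
#' times the recall increment (a step integral, robust to ties).
#'
#' @inheritParams auroc
#' @return The AUPRC, or (with `curve`) a list `auc`, `points`.
#' @export
auprc <- function(scores, labels, curve = FALSE) {
  pr <- pr_points(scores, labels)
  auc <- sum(diff(c(0, pr$recall)) * pr$precision)
  if (curve) list(auc = auc, points = pr) else auc
}

roc_points <- function(scores, labels) {
  check_two_classes(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cut only between distinct scores so ties share one operating point
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1)[keep]
  fp <- cumsum(y == 0)[keep]
  data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
}

pr_points <- function(scores, labels) {
  check_two_classes(labels)
  np <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1)[keep]
  pred <- seq_along(s)[keep]
  data.frame(recall = tp / np, precision = tp / pred)
}

check_two_classes <- function(labels) {
  stopifnot(all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute a ranking curve")
  }
}

#' Evaluate a trained model on a labeled test set
#'
#' Scores the test set with the replicate-mean prediction, then computes the
#' full metric panel: ACC, PRE, recall, F-value, MCC at the threshold, plus
#' AUROC/AUPRC with their curve points.
#'
#' @param object An [activity_model()].
#' @param newdata Test [compound_set()] or feature list.
#' @param labels Binary labels; defaults to the labels carried by `newdata`.
#' @param threshold Decision threshold for the confusion metrics.
#' @return Object of class `metric_report`: `acc`, `pre`, `recall`,
#'   `f_value`, `mcc`, `auroc`, `auprc`, `roc_points`, `pr_points`,
#'   `counts`, `threshold`, `degenerate`.
#' @export
evaluate_model <- function(object, newdata, labels = NULL, threshold = 0.5) {
  scores <- predict(object, newdata)
  if (is.null(labels)) {
    labels <- if (inherits(newdata, "compound_set")) newdata$label
              else newdata$labels
  }
  if (is.null(labels) || anyNA(labels)) stop("test labels are required")
  metric_report(scores, labels, threshold = threshold)
}

#' Metric panel from scores and labels
#' @param scores,labels,threshold As in [confusion_counts()].
#' @return A `metric_report` (see [evaluate_model()]).
#' @export
metric_report <- function(scores, labels, threshold = 0.5) {
  cc <- confusion_counts(scores, labels, threshold)
  m <- classification_metrics(cc)
  ro <- auroc(scores, labels, curve = TRUE)
  pr <- auprc(scores, labels, curve = TRUE)
  structure(list(acc = m$acc, pre = m$pre, recall = m$recall,
                 f_value = m$f_value, mcc = m$mcc,
                 auroc = ro$auc, auprc = pr$auc,
                 roc_points = ro$points, pr_points = pr$points,
                 counts = cc, threshold = threshold,
                 degenerate = attr(m, "degenerate")),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report (threshold %.2f): n = %d\n", x$threshold,
              x$counts$TP + x$counts$FP + x$counts$FN + x$counts$TN))
  cat(sprintf("  ACC %.3f  PRE %.3f  recall %.3f  F-value %.3f  MCC %.3f\n",
              x$acc, x$pre, x$recall, x$f_value, x$mcc))
  cat(sprintf("  AUROC %.3f  AUPRC %.3f\n", x$auroc, x$auprc))
  if (length(x$degenerate)) {
    cat("  degenerate (zero-denominator) metrics:",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a metric report to JSON (+ curve CSVs)
#'
#' @param report A `metric_report`.
#' @param path JSON output path; curve CSVs are written alongside with
#'   suffixes `_roc.csv` and `_pr.csv`.
#' @export
write_metric_report <- function(report, path) {
  scalars <- report[c("acc", "pre", "recall", "f_value", "mcc",
                      "auroc", "auprc", "threshold")]
  scalars$counts <- unclass(report$counts)
  scalars$degenerate <- report$degenerate
  jsonlite::write_json(scalars, path, auto_unbox = TRUE, digits = NA)
  stem <- sub("\\.json$", "", path)
  utils::write.csv(report$roc_points, paste0(stem, "_roc.csv"), row.names = FALSE)
  utils::write.csv(report$pr_points, paste0(stem, "_pr.csv"), row.names = FALSE)
  invisible(path)
}
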