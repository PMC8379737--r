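# Classification metrics for imbalanced pair prediction: ROC AUC,
# area under the precision-recall curve, and thresholded confusion counts.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a randomly
#' chosen positive outscores a randomly chosen negative, ties counted 1/2.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels 0/1 vector.
#' @return AUC in \code{[0, 1]}.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) convention: the PR curve is traversed at
#' the distinct score thresholds and the area is the recall-weighted sum of
#' precisions, with no linear interpolation between points. Tied scores are
#' grouped at one threshold. A constant score vector therefore yields the
#' positive prevalence.
#'
#' @inheritParams auc_roc
#' @return AUPR in \code{(0, 1]}.
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1)
  if (npos == 0) stop("AUPR undefined: no positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); n_pred <- seq_along(y)
  # keep only the last index of each tied-score block (threshold granularity)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; n_pred <- n_pred[keep]
  prec <- tp / n_pred
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Confusion counts and derived rates at a threshold
#'
#' Predictions with \code{score >= threshold} count as positive. Rates with
#' a zero denominator are reported as \code{NA}, not 0.
#'
#' @inheritParams auc_roc
#' @param threshold Decision threshold in \code{[0, 1]} (or the score scale).
#' @return Named list with \code{tp}, \code{fp}, \code{fn}, \code{tn},
#'   \code{precision}, \code{recall} (TPR) and \code{fpr}.
#' @export
confusion_at <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = rate(tp, tp + fp),
       recall = rate(tp, tp + fn),
       fpr = rate(fp, fp + tn))
}

#' Metric report for a set of scored pairs
#'
#' @inheritParams confusion_at
#' @return Object of class \code{ddi_metrics}: \code{auc}, \code{aupr},
#'   \code{prevalence}, \code{n}, and the confusion summary at
#'   \code{threshold}.
#' @export
metric_report <- function(scores, labels, threshold = 0.5) {
  structure(c(list(auc = auc_roc(scores, labels),
                   aupr = aupr(scores, labels),
                   prevalence = mean(as.integer(labels)),
                   n = length(labels),
                   threshold = threshold),
              confusion_at(scores, labels, threshold)),
            class = "ddi_metrics")
}

#' @export
print.ddi_metrics <- function(x, ...) {
  cat(sprintf("AUC %.4f | AUPR %.4f | prevalence %.4f | n = %d\n",
              x$auc, x$aupr, x$prevalence, x$n))
  cat(sprintf("at threshold %.2f: TP %d FP %d FN %d TN %d\n",
              x$threshold, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' External confirmation rate of top predictions
#'
#' Reads a TSV of top-ranked novel predictions annotated with the
#' interaction text found in an external DDI database (one row per drug
#' pair, column \code{interaction}) and returns the fraction of rows whose
#' annotation is not \code{"No interactions"}. The package ships such a
#' lookup for the 20 highest-ranked novel predictions on the 548-drug
#' benchmark, annotated against DrugBank
#' (\code{system.file("extdata", "ds1_top20_drugbank_lookup.tsv",
#' package = "ddinet")}).
#'
#' @param path TSV file with at least a column named \code{interaction}.
#' @return Fraction in \code{[0, 1]} of externally confirmed rows.
#' @export
external_confirmation_rate <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!"interaction" %in% names(df))
    stop("expected a column named 'interaction' in ", path, call. = FALSE)
  mean(trimws(df$interaction) != "No interactions")
}
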