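# Binary-classification metric suite and multi-run aggregation.

#' Confusion-matrix point metrics
#'
#' Computes accuracy, sensitivity (recall, TP/(TP+FN)), specificity
#' (TN/(TN+FP)), and F1 (harmonic mean of precision and recall) from binary
#' labels and predictions, plus AUC-ROC when continuous scores are supplied.
#' Zero-denominator conventions: sensitivity/specificity with an empty class
#' are reported as `NA` with an `undefined` flag; F1 is 0 when precision and
#' recall are both 0.
#'
#' @param labels Binary ground-truth vector (0/1).
#' @param predictions Binary predicted labels (0/1).
#' @param scores Optional continuous scores for the positive class (for
#'   AUC).
#' @return A `metrics_report`: list with `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `auc`, `counts` (TP/FP/TN/FN), `n`, and
#'   `undefined` (names of metrics hit by zero denominators).
#' @export
confusion_metrics <- function(labels, predictions, scores = NULL) {
  if (length(labels) == 0) stop("empty input")
  stopifnot(length(labels) == length(predictions),
            all(labels %in% 0:1), all(predictions %in% 0:1))
  tp <- sum(labels == 1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  undefined <- character()
  sens <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { undefined <- c(undefined, "specificity"); NA_real_ }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (is.na(sens)) 0 else sens
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  auc <- if (!is.null(scores) && length(unique(labels)) == 2) {
    auc_roc(labels, scores)
  } else NA_real_
  structure(list(accuracy = (tp + tn) / length(labels), sensitivity = sens,
                 specificity = spec, f1 = f1, auc = auc,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 n = length(labels), undefined = undefined),
            class = "metrics_report")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with midrank handling of ties:
#' the probability that a random positive outscores a random negative, with
#' ties counting one half.
#'
#' @param labels Binary ground-truth vector (0/1; both classes required).
#' @param scores Continuous scores, larger = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate metric reports across replicate runs
#'
#' Per-metric mean and sample standard deviation (ddof = 1) across runs; for
#' a single run the sd is reported as 0 with the `single_run` flag set.
#'
#' @param reports List of `metrics_report` objects with identical metric
#'   keys.
#' @return List of class `metrics_aggregate` with `mean`, `sd`, `per_run`
#'   (data frame), `n_runs`, `single_run`.
#' @export
aggregate_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  keys <- c("accuracy", "sensitivity", "specificity", "f1", "auc")
  per_run <- do.call(rbind, lapply(reports, function(r) {
    as.data.frame(r[keys])
  }))
  mu <- vapply(keys, function(k) mean(per_run[[k]]), 0)
  sdv <- if (nrow(per_run) > 1) {
    vapply(keys, function(k) stats::sd(per_run[[k]]), 0)
  } else {
    stats::setNames(rep(0, length(keys)), keys)
  }
  structure(list(mean = mu, sd = sdv, per_run = per_run,
                 n_runs = length(reports), single_run = length(reports) == 1L),
            class = "metrics_aggregate")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (n = %d): accuracy %.3f, sensitivity %s, specificity %s, F1 %.3f, AUC %s\n",
              x$n, x$accuracy,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.3f", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.3f", x$specificity)),
              x$f1, ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  cat(sprintf("  counts: TP %d FP %d TN %d FN %d\n",
              x$counts[["TP"]], x$counts[["FP"]], x$counts[["TN"]], x$counts[["FN"]]))
  invisible(x)
}

#' @export
print.metrics_aggregate <- function(x, ...) {
  cat(sprintf("metrics over %d run(s)%s:\n", x$n_runs,
              if (x$single_run) " [single run, sd reported as 0]" else ""))
  for (k in names(x$mean)) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", k, x$mean[[k]], x$sd[[k]]))
  }
  invisible(x)
}

#' Subject-level majority-vote report
#'
#' Secondary aggregation: each subject's windows vote; ties go to high-risk.
#'
#' @param labels Window labels (0/1).
#' @param predictions Window predictions (0/1).
#' @param subject_ids Subject id per window.
#' @param scores Optional window scores (averaged per subject for AUC).
#' @return A `metrics_report` at subject level.
#' @export
subject_vote_metrics <- function(labels, predictions, subject_ids, scores = NULL) {
  agg <- function(v, f) as.numeric(tapply(v, subject_ids, f))
  lab_s <- agg(labels, function(x) round(mean(x)))
  pred_s <- agg(predictions, function(x) as.integer(mean(x) >= 0.5))
  sc_s <- if (!is.null(scores)) agg(scores, mean) else NULL
  confusion_metrics(lab_s, pred_s, sc_s)
}
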