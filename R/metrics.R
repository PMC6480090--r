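#' Tally a 2x2 confusion matrix
#'
#' The fall class is positive: `tp` counts true falls predicted as falls,
#' `tn` true ADLs predicted as ADLs, `fp` ADLs predicted as falls, `fn`
#' falls predicted as ADLs.
#'
#' @param truth,predicted character vectors of equal length with values in
#'   `{"fall", "adl"}`.
#' @return object of class `"confusion_counts"`: named integer vector
#'   `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 1L)
    fallcnn_error("bad_argument", "truth and predicted must have equal length >= 1")
  if (!all(c(truth, predicted) %in% c("fall", "adl")))
    fallcnn_error("bad_argument", "labels must be 'fall' or 'adl'")
  structure(c(tp = sum(truth == "fall" & predicted == "fall"),
              fp = sum(truth == "adl" & predicted == "fall"),
              tn = sum(truth == "adl" & predicted == "adl"),
              fn = sum(truth == "fall" & predicted == "adl")),
            class = "confusion_counts")
}

as_counts <- function(c) {
  if (inherits(c, "confusion_counts") ||
      (is.numeric(c) && all(c("tp", "fp", "tn", "fn") %in% names(c)))) {
    if (any(c < 0)) fallcnn_error("bad_argument", "counts must be non-negative")
    return(c)
  }
  fallcnn_error("bad_argument", "expected confusion counts (tp, fp, tn, fn)")
}

# Ratio with the batch-evaluation convention for an empty denominator:
# return 0 and flag the value as undefined rather than aborting.
safe_ratio <- function(num, den) {
  if (den == 0) structure(0, undefined = TRUE) else num / den
}

#' Classification accuracy
#'
#' `(tp + tn) / (tp + fp + tn + fn)`, the rate of correct classification.
#'
#' @param c confusion counts from [confusion_counts()] (or a named vector
#'   with `tp`, `fp`, `tn`, `fn`).
#' @return proportion in `[0, 1]`.
#' @export
accuracy <- function(c) {
  c <- as_counts(c)
  total <- sum(c[c("tp", "fp", "tn", "fn")])
  if (total == 0) fallcnn_error("bad_argument", "empty confusion table")
  unname((c[["tp"]] + c[["tn"]]) / total)
}

#' Precision (positive predictive value)
#'
#' `tp / (tp + fp)`: of the windows flagged as falls, the fraction that
#' really are falls. When no window is flagged (`tp + fp = 0`) the value is
#' 0 with attribute `undefined = TRUE`.
#'
#' @inheritParams accuracy
#' @return proportion in `[0, 1]`.
#' @export
precision <- function(c) {
  c <- as_counts(c)
  safe_ratio(c[["tp"]], c[["tp"]] + c[["fp"]])
}

#' Sensitivity (true positive rate, recall)
#'
#' `tp / (tp + fn)`: the probability that an actual fall is detected.
#' Undefined (0 with flag) when there are no actual falls.
#'
#' @inheritParams accuracy
#' @return proportion in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  c <- as_counts(c)
  safe_ratio(c[["tp"]], c[["tp"]] + c[["fn"]])
}

#' Specificity (true negative rate)
#'
#' `tn / (tn + fp)`: the probability that an actual ADL is not flagged as a
#' fall. Undefined (0 with flag) when there are no actual ADLs.
#'
#' @inheritParams accuracy
#' @return proportion in `[0, 1]`.
#' @export
specificity <- function(c) {
  c <- as_counts(c)
  safe_ratio(c[["tn"]], c[["tn"]] + c[["fp"]])
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, a correlation
#' between truth and prediction that stays informative under class
#' imbalance. If any factor of the denominator is zero the value is 0 with
#' attribute `undefined = TRUE` (the conventional limit).
#'
#' @inheritParams accuracy
#' @return value in `[-1, 1]`.
#' @export
mcc <- function(c) {
  c <- as_counts(c)
  tp <- c[["tp"]]; fp <- c[["fp"]]; tn <- c[["tn"]]; fn <- c[["fn"]]
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(structure(0, undefined = TRUE))
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Full five-metric evaluation report
#'
#' @param c confusion counts, or a `truth` label vector when `predicted` is
#'   also given.
#' @param predicted optional predicted label vector (same length as `c`).
#' @return object of class `"metrics_report"`: list with `accuracy`,
#'   `precision`, `sensitivity`, `specificity`, `mcc` and the underlying
#'   `counts`. Printed as percentages (two decimals) for the four rate
#'   metrics and four decimals for MCC.
#' @export
metrics_report <- function(c, predicted = NULL) {
  if (!is.null(predicted)) c <- confusion_counts(c, predicted)
  c <- as_counts(c)
  structure(list(accuracy = accuracy(c), precision = precision(c),
                 sensitivity = sensitivity(c), specificity = specificity(c),
                 mcc = mcc(c), counts = c),
            class = "metrics_report")
}

fmt_metric <- function(name, value) {
  flag <- if (isTRUE(attr(value, "undefined"))) " (undefined)" else ""
  if (name == "mcc") sprintf("%.4f%s", as.numeric(value), flag)
  else sprintf("%.2f%s", 100 * as.numeric(value), flag)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Fall-detection metrics (fall = positive class)\n")
  cat(sprintf("  counts: tp=%d fp=%d tn=%d fn=%d\n",
              x$counts[["tp"]], x$counts[["fp"]],
              x$counts[["tn"]], x$counts[["fn"]]))
  for (m in c("accuracy", "precision", "sensitivity", "specificity"))
    cat(sprintf("  %-12s %s\n", m, fmt_metric(m, x[[m]])))
  cat(sprintf("  %-12s %s\n", "mcc", fmt_metric("mcc", x$mcc)))
  invisible(x)
}
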