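# Confusion-matrix construction and micro/macro evaluation metrics.
#
# The micro forms pool one-vs-rest TP/TN/FP/FN counts across classes before
# forming each ratio; the macro forms average the per-class ratios
# unweighted. For any multiclass confusion matrix the micro precision and
# micro recall both collapse to the diagonal fraction (each example
# contributes exactly one FP and one FN when misclassified).

#' Build a confusion matrix
#'
#' @param actual,predicted equal-length vectors of 0-based labels in
#'   `[0, C)`.
#' @param C number of classes.
#' @return object of class `confusion_matrix`: a `C x C` integer matrix,
#'   rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted, C) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length")
  }
  stopifnot(C >= 1)
  if (length(actual) > 0 &&
      (any(actual < 0 | actual >= C) || any(predicted < 0 | predicted >= C))) {
    stop("labels out of range [0, C)")
  }
  m <- matrix(0L, C, C,
              dimnames = list(actual = 0:(C - 1), predicted = 0:(C - 1)))
  if (length(actual) > 0) {
    t <- table(factor(actual, levels = 0:(C - 1)),
               factor(predicted, levels = 0:(C - 1)))
    m[] <- as.integer(t)
  }
  structure(m, class = c("confusion_matrix", class(m)))
}

ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  list(tp = tp, tn = tn, fp = fp, fn = fn, total = total)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s has zero denominator; reporting 0", what))
    return(0)
  }
  num / den
}

#' Micro-averaged metrics
#'
#' Pools per-class one-vs-rest TP/TN/FP/FN across classes, then forms
#' accuracy `(sTP+sTN)/(sTP+sTN+sFP+sFN)`, recall `sTP/(sTP+sFN)`,
#' precision `sTP/(sTP+sFP)` and F1 `2*Pr*Re/(Pr+Re)`.
#'
#' @param cm a [confusion_matrix].
#' @return named list `accuracy, precision, recall, f1`.
#' @export
micro_metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  k <- ovr_counts(cm)
  stp <- sum(k$tp); stn <- sum(k$tn); sfp <- sum(k$fp); sfn <- sum(k$fn)
  pr <- safe_ratio(stp, stp + sfp, "micro precision")
  re <- safe_ratio(stp, stp + sfn, "micro recall")
  list(
    accuracy = safe_ratio(stp + stn, stp + stn + sfp + sfn, "micro accuracy"),
    precision = pr,
    recall = re,
    f1 = if (pr + re == 0) 0 else 2 * pr * re / (pr + re)
  )
}

#' Macro-averaged metrics
#'
#' Per-class one-vs-rest accuracy, precision and recall averaged unweighted
#' over classes; F1 is the harmonic mean of the reported macro precision and
#' macro recall. Requires at least two classes.
#'
#' @param cm a [confusion_matrix].
#' @return named list `accuracy, precision, recall, f1`.
#' @export
macro_metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  if (nrow(cm) < 2) stop("macro metrics need at least two classes")
  k <- ovr_counts(cm)
  per <- function(num, den, what) {
    mapply(function(n, d, i) safe_ratio(n, d, sprintf("%s class %d", what, i)),
           num, den, seq_along(num) - 1L)
  }
  pr <- mean(per(k$tp, k$tp + k$fp, "macro precision"))
  re <- mean(per(k$tp, k$tp + k$fn, "macro recall"))
  list(
    accuracy = mean((k$tp + k$tn) / k$total),
    precision = pr,
    recall = re,
    f1 = if (pr + re == 0) 0 else 2 * pr * re / (pr + re)
  )
}

#' Write metrics as JSON and the confusion matrix as CSV
#'
#' @param cm a [confusion_matrix].
#' @param task,split labels recorded in the JSON.
#' @param out_prefix path prefix; writes `<prefix>_metrics.json` and
#'   `<prefix>_confusion.csv`.
#' @return list with both metric sets and the file paths, invisibly.
#' @export
write_metrics <- function(cm, task, split, out_prefix) {
  res <- list(
    list(task = task, split = split, averaging = "micro", micro_metrics(cm)),
    list(task = task, split = split, averaging = "macro", macro_metrics(cm))
  )
  res <- lapply(res, function(r) c(r[1:3], r[[4]]))
  jpath <- paste0(out_prefix, "_metrics.json")
  cpath <- paste0(out_prefix, "_confusion.csv")
  jsonlite::write_json(res, jpath, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(unclass(cm)), cpath)
  invisible(list(metrics = res, json = jpath, csv = cpath))
}
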