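#' Confusion matrix for binary R-gene classification
#'
#' @param labels True labels (factor or character, `"R-gene"` positive).
#' @param predicted Predicted labels, same encoding.
#' @return A `confusion_matrix` object with integer counts `TP`, `FP`, `TN`,
#'   `FN` (positive class = R-gene).
#' @export
confusion <- function(labels, predicted) {
  labels <- factor(as.character(labels), levels = c("non-R-gene", "R-gene"))
  predicted <- factor(as.character(predicted), levels = c("non-R-gene", "R-gene"))
  if (length(labels) != length(predicted)) {
    stop("labels and predictions differ in length")
  }
  if (anyNA(labels) || anyNA(predicted)) stop("labels must be 'R-gene' or 'non-R-gene'")
  pos <- labels == "R-gene"
  ppos <- predicted == "R-gene"
  confusion_matrix(TP = sum(pos & ppos), FP = sum(!pos & ppos),
                   TN = sum(!pos & !ppos), FN = sum(pos & !ppos))
}

#' @rdname confusion
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(c("true R-gene", "true non-R-gene"),
                              c("pred R-gene", "pred non-R-gene")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and overall accuracy
#'
#' `SN = TP / (TP + FN)`, `SP = TN / (TN + FP)` (fractions) and
#' `Acc = 100 * (TP + TN) / m` (percent).  An empty class makes the
#' corresponding rate undefined: it is reported as `NaN` with a warning,
#' never silently zeroed.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector `c(SN, SP, Acc)`.
#' @examples
#' metric_sn_sp_acc(confusion_matrix(TP = 10, FP = 0, TN = 10, FN = 0))
#' @export
metric_sn_sp_acc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$TP + cm$FP + cm$TN + cm$FN
  if (m == 0L) stop("empty confusion matrix")
  sn <- if (cm$TP + cm$FN > 0L) cm$TP / (cm$TP + cm$FN) else {
    warning("no positive instances: SN undefined"); NaN
  }
  sp <- if (cm$TN + cm$FP > 0L) cm$TN / (cm$TN + cm$FP) else {
    warning("no negative instances: SP undefined"); NaN
  }
  c(SN = sn, SP = sp, Acc = 100 * (cm$TP + cm$TN) / m)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.  When any
#' marginal is zero the denominator vanishes; by the documented convention
#' the function then returns 0 with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return MCC in `[-1, 1]`.
#' @export
metric_mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$TP); fp <- as.numeric(cm$FP)
  tn <- as.numeric(cm$TN); fn <- as.numeric(cm$FN)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(marg == 0)) {
    warning("zero marginal in confusion matrix: MCC reported as 0 by convention")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(prod(marg))
}

#' ROC area by the rank statistic
#'
#' The area under the ROC curve computed as the concordance probability: the
#' proportion of (positive, negative) score pairs ranked correctly, ties
#' counted half.  Equivalent to the Wilcoxon-Mann-Whitney statistic and, on
#' tie-free scores, to trapezoidal integration of the ROC curve.
#'
#' @param labels True labels (`"R-gene"` positive).
#' @param scores Numeric classifier scores, higher = more positive.
#' @return AUC fraction in `[0, 1]`.
#' @export
metric_roc_area <- function(labels, scores) {
  labels <- factor(as.character(labels), levels = c("non-R-gene", "R-gene"))
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  n_pos <- sum(labels == "R-gene")
  n_neg <- sum(labels == "non-R-gene")
  if (n_pos == 0L || n_neg == 0L) stop("ROC area requires both classes present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == "R-gene"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full evaluation report from labels and scores
#'
#' Thresholds scores at 0.5, builds the confusion matrix and assembles
#' SN/SP/Acc/MCC/ROC-area.
#'
#' @param labels True labels.
#' @param scores Scores in `[0, 1]` (probability of the R-gene class).
#' @param protocol Evaluation protocol tag (`"holdout"`, `"cv10"`, ...).
#' @param seed Seed recorded in the report, if any.
#' @return An `eval_report` object: list with `confusion`, `SN`, `SP`, `Acc`,
#'   `MCC`, `ROC_area`, `protocol`, `seed`, `n`.
#' @export
eval_report <- function(labels, scores, protocol = "holdout", seed = NA_integer_) {
  predicted <- ifelse(scores >= 0.5, "R-gene", "non-R-gene")
  cm <- confusion(labels, predicted)
  ssa <- suppressWarnings(metric_sn_sp_acc(cm))
  roc <- tryCatch(metric_roc_area(labels, scores), error = function(e) NaN)
  structure(list(confusion = cm,
                 SN = unname(ssa["SN"]), SP = unname(ssa["SP"]),
                 Acc = unname(ssa["Acc"]),
                 MCC = suppressWarnings(metric_mcc(cm)),
                 ROC_area = roc,
                 protocol = protocol, seed = seed,
                 n = cm$TP + cm$FP + cm$TN + cm$FN),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s, n = %d):\n", x$protocol, x$n))
  cat(sprintf("  SN = %.4f  SP = %.4f  Acc = %.4f%%  MCC = %.4f  ROC area = %.4f\n",
              x$SN, x$SP, x$Acc, x$MCC, x$ROC_area))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- list(protocol = report$protocol, seed = report$seed, n = report$n,
              confusion = report$confusion[c("TP", "FP", "TN", "FN")],
              SN = report$SN, SP = report$SP, Acc = report$Acc,
              MCC = report$MCC, ROC_area = report$ROC_area)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
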