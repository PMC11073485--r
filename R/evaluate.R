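#' Confusion matrix from predicted and true labels
#'
#' @param predicted Logical vector, `TRUE` = predicted positive (low LVEF).
#' @param truth Logical vector of the same length, `TRUE` = positive.
#' @return Object of class `if_confusion` with counts `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_matrix <- function(predicted, truth) {
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  if (length(predicted) != length(truth))
    abort_data("predicted and truth must have equal length")
  if (anyNA(predicted) || anyNA(truth)) abort_data("labels contain NA")
  structure(list(TP = sum(predicted & truth), FP = sum(predicted & !truth),
                 TN = sum(!predicted & !truth), FN = sum(!predicted & truth)),
            class = "if_confusion")
}

#' @export
print.if_confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`. A metric whose denominator is zero
#' is returned as `NA` (an explicit undefined marker, not a propagated
#' `NaN`).
#'
#' @param cm An [confusion_matrix()] result.
#' @return Named list `sensitivity`, `specificity`, `accuracy`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "if_confusion"))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = safe(cm$TP, cm$TP + cm$FN),
       specificity = safe(cm$TN, cm$TN + cm$FP),
       accuracy = safe(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' `score >= threshold`), grouping tied scores, which yields a monotone
#' curve from (0,0) to (1,1). The AUC is the trapezoidal area, which equals
#' the Mann-Whitney rank statistic: the probability that a random positive
#' outscores a random negative, ties counting one half.
#'
#' @param scores Numeric ranking scores (higher = more likely positive).
#' @param labels Logical truth labels; both classes must be present.
#' @return List with `roc_points` (data frame `fpr`, `tpr`, `threshold`)
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    abort_data("scores and labels must have equal length")
  nP <- sum(labels); nN <- sum(!labels)
  if (nP == 0L || nN == 0L)
    abort_data("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  pts <- data.frame(fpr = c(0, fp / nN), tpr = c(0, tp / nP),
                    threshold = c(Inf, s[grp_end]))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(roc_points = pts, auc = auc)
}

#' Leave-one-out cross-validation of a constrained CART classifier
#'
#' Deterministic n-fold validation: for each subject a tree is trained on
#' all other subjects under the same constraints, and the held-out
#' subject's leaf score and label are recorded. Folds with a single class
#' train a single-leaf tree (not an error). The per-subject output is
#' invariant to the ordering of the input table.
#'
#' @param data Subject feature table with predictor columns, a logical
#'   label column, and `subject_id`.
#' @param predictors Predictor column names.
#' @param label Label column name.
#' @param max_splits,min_split_size Passed to [train_cart()].
#' @return Data frame `subject_id`, `score` (held-out leaf positive
#'   fraction), `predicted` (score > 0.5), `truth`, in input order.
#' @export
loocv <- function(data, predictors, label = "label",
                  max_splits = NULL, min_split_size = 11L) {
  n <- nrow(data)
  if (n < 3L) abort_data("LOOCV needs at least 3 subjects")
  out <- lapply(seq_len(n), function(i) {
    tr <- train_cart(data[-i, , drop = FALSE], predictors, label,
                     max_splits = max_splits, min_split_size = min_split_size)
    pr <- predict(tr, data[i, , drop = FALSE])
    data.frame(subject_id = as.character(data$subject_id[i]),
               score = pr$score, predicted = pr$score > 0.5,
               truth = as.logical(data[[label]][i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble a screening report
#'
#' Pools per-subject scores into one confusion matrix (score threshold 0.5),
#' the three summary metrics, and the ROC/AUC.
#'
#' @param scores Numeric per-subject scores.
#' @param truth Logical truth labels.
#' @param subject_id Optional identifiers.
#' @param threshold Score threshold for the confusion matrix.
#' @return Object of class `screening_report`: `confusion`, `metrics`,
#'   `auc`, `roc_points`, `per_subject`.
#' @export
screening_report <- function(scores, truth, subject_id = NULL, threshold = 0.5) {
  truth <- as.logical(truth)
  predicted <- scores > threshold
  cm <- confusion_matrix(predicted, truth)
  roc <- if (sum(truth) > 0 && sum(!truth) > 0) roc_auc(scores, truth) else NULL
  structure(
    list(confusion = cm, metrics = metrics(cm),
         auc = if (is.null(roc)) NA_real_ else roc$auc,
         roc_points = if (is.null(roc)) NULL else roc$roc_points,
         per_subject = data.frame(
           subject_id = subject_id %||% as.character(seq_along(scores)),
           score = scores, predicted = predicted, truth = truth,
           stringsAsFactors = FALSE)),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  m <- x$metrics
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat("<screening_report>\n")
  print(x$confusion)
  cat(sprintf("  sensitivity = %s, specificity = %s, accuracy = %s, AUC = %s\n",
              fmt(m$sensitivity), fmt(m$specificity), fmt(m$accuracy),
              fmt(x$auc)))
  invisible(x)
}
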