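# ROC/AUC and confusion summaries for any scoring or labeling rule.
# The empirical ROC and its trapezoidal area come from pROC; with the
# trapezoid over all distinct thresholds the AUC equals the Mann-Whitney
# statistic (ties counting 1/2) divided by n1 * n0.

#' Empirical ROC curve and AUC
#'
#' @param scores Numeric score per subject; missing scores are excluded
#'   and their count reported.
#' @param labels Vector of labels.
#' @param positive Label of the positive class; everything else is
#'   negative.
#' @param direction `">"` if higher scores indicate the positive class,
#'   `"<"` if lower scores do.
#' @return Object of class `roc_curve`: `points` (data frame `fpr`, `tpr`
#'   from (0,0) to (1,1)), `auc`, `direction`, `n_pos`, `n_neg`,
#'   `n_missing`.
#' @export
roc_auc <- function(scores, labels, positive, direction = c(">", "<")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores)
  n_missing <- sum(!keep)
  scores <- scores[keep]
  resp <- labels[keep] == positive
  if (!any(resp) || all(resp))
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  # pROC's direction "<" means controls < cases, i.e. higher score = positive
  r <- pROC::roc(response = resp, predictor = scores,
                 direction = if (direction == ">") "<" else ">",
                 levels = c(FALSE, TRUE), quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, auc = as.numeric(r$auc), direction = direction,
                 n_pos = sum(resp), n_neg = sum(!resp),
                 n_missing = n_missing),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f  (%d positive, %d negative, %d missing excluded)\n",
              x$auc, x$n_pos, x$n_neg, x$n_missing))
  invisible(x)
}

#' Confusion matrix with sensitivity and specificity
#'
#' Sensitivity is the fraction of positive-class subjects predicted
#' positive; specificity the fraction of all non-positive subjects not
#' predicted positive.  Exact fractions are retained; the print method
#' shows percentages rounded to the nearest integer.
#'
#' @param pred,truth Label vectors of equal length.
#' @param positive Label of the positive class.
#' @return Object of class `confusion_summary`: `table` (predicted x
#'   true counts), `sensitivity`, `specificity` (fractions), `n`.
#' @export
confusion <- function(pred, truth, positive) {
  if (length(pred) != length(truth))
    stop("pred and truth differ in length", call. = FALSE)
  lev <- sort(unique(c(pred, truth)))
  tab <- table(predicted = factor(pred, lev), true = factor(truth, lev))
  is_pos_true <- truth == positive
  is_pos_pred <- pred == positive
  structure(list(table = tab,
                 sensitivity = sum(is_pos_pred & is_pos_true) / sum(is_pos_true),
                 specificity = sum(!is_pos_pred & !is_pos_true) / sum(!is_pos_true),
                 positive = positive, n = length(pred)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  print(x$table)
  cat(sprintf("sensitivity %d%%, specificity %d%% (positive class: %s)\n",
              round(100 * x$sensitivity), round(100 * x$specificity),
              x$positive))
  invisible(x)
}

#' Write ROC operating points as delimited text
#'
#' @param roc A [roc_auc()] result.
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path, sep = ",") {
  utils::write.table(roc$points, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
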