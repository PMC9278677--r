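# Evaluation: confusion counts with FAIL as the positive class,
# sensitivity/specificity, regression accuracy, and the combined report.

#' Confusion counts with FAIL as the positive class
#'
#' A QA prediction model exists to catch failing deliveries, so the FAIL
#' label is the positive class: TP = predicted FAIL and measured FAIL,
#' TN = predicted PASS and measured PASS, FP = predicted FAIL but measured
#' PASS, FN = predicted PASS but measured FAIL.
#'
#' @param predicted,measured factors with levels `FAIL`, `PASS`.
#' @return Named integer vector `TP, FP, TN, FN`.
#' @export
confusion_counts <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured))
  p_fail <- predicted == "FAIL"; m_fail <- measured == "FAIL"
  c(TP = sum(p_fail & m_fail), FP = sum(p_fail & !m_fail),
    TN = sum(!p_fail & !m_fail), FN = sum(!p_fail & m_fail))
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN) * 100`; `specificity = TN / (TN + FP) * 100`.
#' When a class is empty the affected metric is `NA` (undefined), not 0.
#'
#' @param cm named counts `TP, FP, TN, FN` (from [confusion_counts()]).
#' @param digits rounding for reporting (default 2, half-up as in standard
#'   table formatting).
#' @return Named numeric vector `sensitivity, specificity` (percent).
#' @export
sensitivity_specificity <- function(cm, digits = 2) {
  sens <- if (cm[["TP"]] + cm[["FN"]] > 0)
    100 * cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]) else NA_real_
  spec <- if (cm[["TN"]] + cm[["FP"]] > 0)
    100 * cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]) else NA_real_
  round2 <- function(v) if (is.na(v)) v else floor(v * 10^digits + 0.5) / 10^digits
  c(sensitivity = round2(sens), specificity = round2(spec))
}

#' Regression accuracy: RMSE and fraction within +/- 3 GPR points
#'
#' @param predicted,measured equal-length numeric GPR vectors (percent).
#' @param within half-width of the agreement band, GPR percentage points
#'   (default 3; a difference of exactly 3 counts as within).
#' @return Named vector `rmse` (GPR points) and `pct_within` (percent).
#' @export
regression_accuracy <- function(predicted, measured, within = 3) {
  if (length(predicted) != length(measured))
    stop("predicted and measured lengths differ")
  if (!length(predicted)) stop("empty vectors")
  d <- predicted - measured
  c(rmse = sqrt(mean(d^2)),
    pct_within = 100 * mean(abs(d) <= within))
}

#' Evaluate a fitted model on a dataset split
#'
#' Predicts on the chosen split and reports the confusion counts,
#' sensitivity and specificity (FAIL positive); for the regression model
#' additionally RMSE and the percentage of predictions within +/- 3 GPR
#' points, with predicted GPR thresholded at the dataset's warning level
#' for the classification metrics.
#'
#' @param model a `gpr_model`.
#' @param dataset a `qa_dataset`.
#' @param criterion `"gpr_2_2"` or `"gpr_3_2"`.
#' @param split `"test"` (default), `"train"` or `"all"`.
#' @param top_k importance ranking length (default 5).
#' @return Object of class `qa_eval`: list with `confusion`, `sensitivity`,
#'   `specificity`, `rmse`, `pct_within_3` (regression only), `importance`,
#'   `n`, `criterion`, `split`.
#' @export
evaluate_model <- function(model, dataset, criterion = c("gpr_2_2", "gpr_3_2"),
                           split = c("test", "train", "all"), top_k = 5) {
  criterion <- match.arg(criterion)
  split <- match.arg(split)
  d <- dataset$data
  if (split != "all") d <- d[d$split == split, , drop = FALSE]
  if (!nrow(d)) stop("empty split: ", split)
  wl <- dataset$warning_levels[[criterion]]
  measured <- label_gpr(d[[criterion]], wl)
  rmse <- NA_real_; pct3 <- NA_real_
  if (model$method == "adaboost") {
    predicted <- predict(model, d)
  } else {
    pred_gpr <- predict(model, d)
    predicted <- label_gpr(pred_gpr, wl)
    acc <- regression_accuracy(pred_gpr, d[[criterion]])
    rmse <- acc[["rmse"]]; pct3 <- acc[["pct_within"]]
  }
  cm <- confusion_counts(predicted, measured)
  ss <- sensitivity_specificity(cm)
  structure(list(
    confusion = cm,
    sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
    rmse = rmse, pct_within_3 = pct3,
    importance = feature_importance(model, top_k),
    n = nrow(d), criterion = criterion, split = split,
    method = model$method
  ), class = "qa_eval")
}

#' @export
print.qa_eval <- function(x, ...) {
  cat("Evaluation (", x$method, ", ", x$criterion, ", ", x$split,
      " split, n = ", x$n, ")\n", sep = "")
  cm <- x$confusion
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d (FAIL positive)\n",
              cm[["TP"]], cm[["FP"]], cm[["TN"]], cm[["FN"]]))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%\n",
              x$sensitivity, x$specificity))
  if (!is.na(x$rmse))
    cat(sprintf("  RMSE %.2f GPR points; %.1f%% within +/-3\n",
                x$rmse, x$pct_within_3))
  cat("  top features: ", paste(names(x$importance), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
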