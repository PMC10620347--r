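# Macro-averaged evaluation. Per-class precision and recall use the
# 0-convention when a denominator is zero; F1 = 2PR/(P+R) (0 when both
# are 0); macro metrics are unweighted means over the task's gold
# classes, so a class never predicted still contributes F1 = 0.

#' Evaluate predictions against gold labels
#'
#' @param predicted,gold Equal-length character vectors of labels.
#' @param classes Gold classes to average over; defaults to the sorted
#'   classes observed in `gold`.
#' @return An object of class `metrics_report`: `accuracy`, `per_class`
#'   (data.frame of precision/recall/f1/support), `macro_precision`,
#'   `macro_recall`, `macro_f1` and the gold x predicted `confusion`
#'   matrix.
#' @export
#' @examples
#' evaluate_predictions(c("A", "A", "B"), c("A", "B", "B"))
evaluate_predictions <- function(predicted, gold, classes = NULL) {
  if (length(predicted) != length(gold)) {
    stop("predicted and gold must have the same length")
  }
  predicted <- as.character(predicted)
  gold <- as.character(gold)
  if (is.null(classes)) classes <- sort(unique(gold))
  all_lv <- sort(unique(c(classes, predicted, gold)))
  conf <- table(factor(gold, levels = all_lv),
                factor(predicted, levels = all_lv))
  conf <- matrix(as.numeric(conf), nrow = length(all_lv),
                 dimnames = list(gold = all_lv, predicted = all_lv))
  per <- t(vapply(classes, function(cls) {
    tp <- conf[cls, cls]
    fp <- sum(conf[, cls]) - tp
    fn <- sum(conf[cls, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f1, support = tp + fn)
  }, numeric(4L)))
  per <- as.data.frame(per)
  structure(list(accuracy = sum(predicted == gold) / length(gold),
                 per_class = per,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 confusion = conf,
                 n = length(gold)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.2f%% (n = %d)\n", 100 * x$accuracy, x$n))
  cat(sprintf("Macro P/R/F1: %.2f / %.2f / %.2f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  print(round(x$per_class, 4L))
  cat("Confusion (gold x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Format a metrics report the way the result tables print
#'
#' Accuracy as a percentage to two decimals, macro-F1 to two decimals.
#'
#' @param x A `metrics_report`.
#' @return Named character vector with `accuracy` and `macro_f1`.
#' @export
format_report_row <- function(x) {
  c(accuracy = sprintf("%.2f", 100 * x$accuracy),
    macro_f1 = sprintf("%.2f", x$macro_f1))
}
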