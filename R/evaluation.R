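#' Confusion matrices and derived metrics
#'
#' `confusion_matrix()` builds a K x K count matrix with rows = true
#' class and columns = predicted class. `ccr()` is the correct
#' classification rate, `100 * trace / total`. `class_metrics()` returns
#' per-class recall (sensitivity), specificity, precision, F1 and error
#' as percentages, derived from the one-vs-rest counts TP, FN, FP, TN
#' (`TN = total - row - column + TP`). `misclassified()` counts the
#' off-diagonal total.
#'
#' An alternative true-negative bookkeeping, `tn = "diagonal"`, counts
#' only the other diagonal entries (the sum of the main diagonal minus
#' the class's own TP) instead of the full complement; it is provided
#' for comparability with sources that use that convention, but the
#' standard complement is the default.
#'
#' @param truth,predicted label vectors of equal length.
#' @param classes class vocabulary (order fixes the matrix layout).
#' @return `confusion_matrix()`: integer matrix of class
#'   `"sv_confusion"`.
#' @examples
#' cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
#' ccr(cm)  # 66.67
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  if (!all(c(truth, predicted) %in% classes)) {
    abort("labels outside the class vocabulary.")
  }
  m <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  structure(matrix(as.integer(m), length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes)),
            class = c("sv_confusion", "matrix", "array"))
}

#' @rdname confusion_matrix
#' @param cm a confusion matrix (any K x K count matrix, K >= 2).
#' @export
ccr <- function(cm) {
  cm <- as_cm(cm)
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix.")
  100 * sum(diag(cm)) / total
}

#' @rdname confusion_matrix
#' @export
misclassified <- function(cm) {
  cm <- as_cm(cm)
  sum(cm) - sum(diag(cm))
}

as_cm <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm) || nrow(cm) < 2 || any(cm < 0)) {
    abort("a confusion matrix must be square, K >= 2, nonnegative.")
  }
  cm
}

#' @rdname confusion_matrix
#' @param tn `"standard"` (complement) or `"diagonal"` (see Details).
#' @export
class_metrics <- function(cm, tn = c("standard", "diagonal")) {
  tn <- match.arg(tn)
  cm <- as_cm(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix.")
  rows <- lapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn_k <- if (tn == "standard") total - tp - fn - fp else {
      sum(diag(cm)) - tp
    }
    safe_pct <- function(num, den) {
      if (den == 0) {
        warn("division by zero in a class metric; returning 0.")
        return(0)
      }
      100 * num / den
    }
    recall <- safe_pct(tp, tp + fn)
    precision <- safe_pct(tp, tp + fp)
    f1 <- if (precision + recall == 0) 0 else {
      2 * precision * recall / (precision + recall)
    }
    tibble(class = classes[k],
           recall = recall,
           specificity = safe_pct(tn_k, tn_k + fp),
           precision = precision,
           f1 = f1,
           error = safe_pct(fn, tp + fn),
           accuracy = safe_pct(tp + tn_k, tp + tn_k + fp + fn))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.sv_confusion <- function(x, ...) {
  cat("<confusion matrix> CCR ", sprintf("%.2f%%", ccr(x)), "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' @rdname confusion_matrix
#' @param x an `"sv_confusion"`.
#' @param ... unused.
#' @export
tidy.sv_confusion <- function(x, ...) class_metrics(x)

#' @rdname confusion_matrix
#' @export
glance.sv_confusion <- function(x, ...) {
  tibble(ccr = ccr(x), misclassified = misclassified(x), n = sum(x))
}

#' One-vs-rest ROC and precision-recall curves
#'
#' `roc_curve()` sweeps the score threshold over a binary ground truth
#' and returns the (FPR, TPR) path; `roc_auc()` is its trapezoidal
#' area. `pr_curve()`/`pr_auc()` do the same in precision-recall space.
#'
#' @param scores numeric score for the positive class.
#' @param truth logical (or 0/1) vector, `TRUE` = positive.
#' @return `roc_curve()`: tibble with `threshold`, `fpr`, `tpr`;
#'   `roc_auc()`, `pr_auc()`: a single number in \[0, 1\].
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (anyNA(scores) || any(!is.finite(scores))) {
    abort("scores must be finite.")
  }
  if (all(truth) || !any(truth)) {
    abort("ROC needs both classes present in `truth`.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  tp <- cumsum(t); fp <- cumsum(!t)
  # collapse threshold ties: keep the last point of each distinct score
  keep <- c(diff(s) != 0, TRUE)
  tibble(threshold = c(Inf, s[keep]),
         fpr = c(0, fp[keep] / sum(!truth)),
         tpr = c(0, tp[keep] / sum(truth)))
}

#' @rdname roc_curve
#' @export
roc_auc <- function(scores, truth) {
  rc <- roc_curve(scores, truth)
  trapezoid(rc$fpr, rc$tpr)
}

#' @rdname roc_curve
#' @export
pr_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (!any(truth)) abort("PR curve needs at least one positive.")
  if (all(truth)) {
    # degenerate but well-defined: precision is 1 everywhere
    return(tibble(threshold = c(Inf, min(scores)),
                  recall = c(0, 1), precision = c(1, 1)))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  tp <- cumsum(t); fp <- cumsum(!t)
  keep <- c(diff(s) != 0, TRUE)
  recall <- tp[keep] / sum(truth)
  precision <- tp[keep] / (tp[keep] + fp[keep])
  tibble(threshold = c(Inf, s[keep]),
         recall = c(0, recall),
         precision = c(if (length(precision)) precision[1] else 1,
                       precision))
}

#' @rdname roc_curve
#' @export
pr_auc <- function(scores, truth) {
  pc <- pr_curve(scores, truth)
  trapezoid(pc$recall, pc$precision)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Summary of a per-iteration metric
#'
#' Mean, sample standard deviation, and the boxplot five-number summary
#' (median, quartiles, and whiskers at 1.5 IQR clamped to the data
#' range).
#'
#' @param values numeric vector (length >= 2).
#' @return one-row tibble.
#' @export
summarize_iterations <- function(values) {
  if (length(values) < 2) abort("need at least 2 values.")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  tibble(mean = mean(values), sd = sd(values),
         median = q[2], q1 = q[1], q3 = q[3],
         whisker_low = min(values[values >= q[1] - 1.5 * iqr]),
         whisker_high = max(values[values <= q[3] + 1.5 * iqr]),
         n = length(values))
}

#' Read a confusion matrix from CSV
#'
#' Expects a header row of class names and one leading column of true
#' class names (the layout written by [write_confusion_csv()]).
#'
#' @param path CSV file.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  structure(matrix(as.integer(m), nrow(m), ncol(m),
                   dimnames = list(true = rownames(df),
                                   predicted = colnames(df))),
            class = c("sv_confusion", "matrix", "array"))
}

#' @rdname read_confusion_csv
#' @param cm confusion matrix.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path)
  invisible(path)
}
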