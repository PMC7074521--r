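#' Plot methods
#'
#' `autoplot()` methods for the package's result objects:
#' an optimizer trace (best fitness per iteration), an experiment
#' (per-iteration CCR and AUC boxplots by classifier), and a confusion
#' matrix (count heatmap). `plot_roc()` overlays one-vs-rest ROC
#' curves.
#'
#' @param object the result object.
#' @param ... unused.
#' @return a ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.optimizer_trace <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration,
                               y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best fitness (MSE)",
                  title = "Optimizer convergence") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.sv_experiment <- function(object, ...) {
  long <- object$metrics |>
    tidyr::pivot_longer(cols = -c("iteration", "classifier"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$classifier,
                                     y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-iteration test metrics") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.sv_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Confusion matrix (CCR %.2f%%)",
                                  ccr(object))) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param scores numeric matrix of class scores (columns = classes).
#' @param truth character vector of true labels.
#' @export
plot_roc <- function(scores, truth) {
  classes <- colnames(scores)
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(scores)))
  curves <- dplyr::bind_rows(lapply(seq_along(classes), function(k) {
    rc <- roc_curve(scores[, k], truth == classes[k])
    rc$class <- sprintf("%s (AUC %.3f)", classes[k],
                        roc_auc(scores[, k], truth == classes[k]))
    rc
  }))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       color = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", alpha = 0.4) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "One-vs-rest ROC") +
    ggplot2::theme_minimal()
}
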