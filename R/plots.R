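#' ROC curve of a screening result
#'
#' @param object an `iec_screen` tibble from [screen_result()].
#' @param ... unused.
#' @return A ggplot object: ROC curve with the chance diagonal.
#' @method autoplot iec_screen
#' @export
autoplot.iec_screen <- function(object, ...) {
  ord <- order(-object$score, seq_len(nrow(object)))
  lab <- object$label[ord]
  tpr <- c(0, cumsum(lab) / sum(lab))
  fpr <- c(0, cumsum(1 - lab) / sum(1 - lab))
  df <- tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", roc_auc(object))) +
    ggplot2::theme_minimal()
}

#' Search-trace plot
#'
#' CV objective against search step, with the incumbent best overlaid.
#'
#' @param object an `iec_tune` object.
#' @param ... unused.
#' @method autoplot iec_tune
#' @export
autoplot.iec_tune <- function(object, ...) {
  df <- object$trace
  df$best_so_far <- cummax(df$cv_f1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cv_f1), alpha = 0.5) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_so_far), colour = "firebrick") +
    ggplot2::labs(x = "Search step", y = "CV F1",
                  title = sprintf("%s random search (%d-fold CV)",
                                  object$algorithm, object$folds)) +
    ggplot2::theme_minimal()
}

#' Grouped feature-importance plot
#'
#' @param report tibble from [tree_importance()].
#' @return A ggplot object: aggregated importance per scoring function,
#'   faceted by interaction group.
#' @export
plot_importance <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = stats::reorder(.data$scoring_function,
                                                  .data$importance),
                               y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::labs(x = NULL, y = paste0("importance (", report$mode[1], ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
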