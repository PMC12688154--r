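# ggplot2 views of the result objects: RFE trace, fold scores, prediction
# scatter and equal-count calibration.

#' Plot an RFE trace
#'
#' Mean cross-validated R-squared (with a +/- 1 sd ribbon) as features
#' are eliminated; the selected round is marked.
#'
#' @param object A `stab_rfe` result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot stab_rfe
#' @export
autoplot.stab_rfe <- function(object, ...) {
  tr <- object$trace
  best <- tr[object$best_round, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$round, y = .data$mean_r2)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_r2 - .data$sd_r2,
                                      ymax = .data$mean_r2 + .data$sd_r2),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::labs(x = "RFE round", y = expression(mean~R^2),
                  title = "Recursive feature elimination",
                  subtitle = sprintf("selected round %d (%d features)",
                                     object$best_round, best$n_features)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation scores
#'
#' @param object A `stab_cv` result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot stab_cv
#' @export
autoplot.stab_cv <- function(object, ...) {
  ggplot2::ggplot(object$fold_scores,
                  ggplot2::aes(x = factor(.data$fold), y = .data$r_squared)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_r2, linetype = 2) +
    ggplot2::labs(x = "fold", y = expression(R^2),
                  title = sprintf("Pair-level %d-fold cross-validation", object$k),
                  subtitle = sprintf("mean R2 = %.3f (sd %.3f)",
                                     object$mean_r2, object$sd_r2)) +
    ggplot2::theme_minimal()
}

#' Prediction scatter for paired predictions
#'
#' Predicted versus true DDG, coloured by record origin, with the
#' identity line.
#'
#' @param predictions Tibble with `ddg`, `pred` and optionally `origin`.
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions) {
  p <- ggplot2::ggplot(predictions,
                       ggplot2::aes(x = .data$ddg, y = .data$pred))
  p <- if ("origin" %in% names(predictions)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$origin), alpha = 0.5)
  } else {
    p + ggplot2::geom_point(alpha = 0.5)
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "experimental DDG (kcal/mol)",
                  y = "predicted DDG (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Equal-count calibration plot
#'
#' Mean predicted versus mean true DDG per equal-count bin, with error
#' bars showing the standard error of the residuals, against the y = x
#' reference.
#'
#' @param pred,truth Numeric vectors.
#' @param bins Number of equal-count bins (default 10).
#' @return A ggplot object.
#' @export
plot_calibration <- function(pred, truth, bins = 10) {
  cal <- binned_calibration(pred, truth, bins)
  ggplot2::ggplot(cal, ggplot2::aes(x = .data$mean_truth, y = .data$mean_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pred - .data$se_residual,
                                        ymax = .data$mean_pred + .data$se_residual),
                           width = 0) +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = "mean experimental DDG per bin (kcal/mol)",
                  y = "mean predicted DDG per bin (kcal/mol)",
                  title = sprintf("Calibration over %d equal-count bins", bins)) +
    ggplot2::theme_minimal()
}
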