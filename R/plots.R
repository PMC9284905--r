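# ggplot2 autoplot() methods.

#' Plot an ROC curve
#'
#' @param object A `roc_result` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate(
      "point",
      x = 1 - object$youden$specificity, y = object$youden$sensitivity,
      shape = 4, size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.2f (%.0f%% CI %.2f-%.2f)", object$auc,
                      100 * object$conf_level, object$ci_low, object$ci_high),
      subtitle = sprintf("x: Youden cut-point %.4g", object$youden$cutpoint)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_result` from [pr_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pr_result
#' @export
autoplot.pr_result <- function(object, ...) {
  prevalence <- object$n_pos / (object$n_pos + object$n_neg)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_hline(yintercept = prevalence, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall (sensitivity)", y = "Precision (PPV)",
                  title = sprintf("PR area %.2f", object$pr_area)) +
    ggplot2::theme_minimal()
}

#' Contour plot of a joint two-threshold accuracy grid
#'
#' @param object A `grid_search_result` from [joint_threshold_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grid_search_result
#' @export
autoplot.grid_search_result <- function(object, ...) {
  long <- tidy(object)
  names(long)[1:2] <- c("t1", "t2")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t1, y = .data$t2,
                                     z = .data$accuracy)) +
    ggplot2::geom_contour_filled(bins = 10) +
    ggplot2::annotate("point", x = object$best$threshold1,
                      y = object$best$threshold2, shape = 4, size = 3) +
    ggplot2::labs(
      x = object$marker1, y = object$marker2, fill = "Accuracy",
      title = sprintf("Best accuracy %d%% at (%.4g, %.4g)",
                      object$best$accuracy_pct, object$best$threshold1,
                      object$best$threshold2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cross-section percent-fat profile with detected boundaries
#'
#' @param object A `cross_section` from [average_cross_section()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cross_section
#' @export
autoplot.cross_section <- function(object, ...) {
  s <- object$strips
  mids <- (s$x_left + s$x_right) / 2
  d <- tibble(x = mids, pct_fm = s$pct_fm, total = s$total_1cm)
  bounds <- tibble(
    x = c(object$outer_left_x, object$inner_left_x,
          object$inner_right_x, object$outer_right_x),
    boundary = c("outer", "inner", "inner", "outer")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$pct_fm)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(
      data = bounds,
      ggplot2::aes(xintercept = .data$x, linetype = .data$boundary),
      colour = "grey40"
    ) +
    ggplot2::labs(x = "x (cm)", y = "% fat mass",
                  linetype = "SFL boundary",
                  title = sprintf("Width %.1f cm, SFL width %.2f cm",
                                  object$abdominal_width, object$sfl_width)) +
    ggplot2::theme_minimal()
}
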