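#' Plot a ROC curve
#'
#' @param object a `usj_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.usj_roc <- function(object, ...) {
  df <- data.frame(fpr = object$one_minus_specificity,
                   tpr = object$sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' Plot training loss curves
#'
#' @param object a `usj_train_log` tibble from [train_network()].
#' @param smooth window of the running-mean smoother (iterations).
#' @param ... unused.
#' @return a ggplot of the segmentation, classification and joint loss
#'   traces.
#' @export
autoplot.usj_train_log <- function(object, smooth = 25, ...) {
  run_mean <- function(x) as.numeric(stats::filter(
    x, rep(1 / smooth, smooth), sides = 1))
  df <- data.frame(
    iteration = rep(object$iteration, 3),
    loss = c(run_mean(object$seg_loss), run_mean(object$cls_loss),
             run_mean(object$joint_loss)),
    component = rep(c("segmentation", "classification", "joint"),
                    each = nrow(object)))
  ggplot2::ggplot(stats::na.omit(df),
                  ggplot2::aes(x = .data$iteration, y = .data$loss,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = sprintf(
      "Loss (running mean, window %d)", smooth)) +
    ggplot2::theme_minimal()
}

#' Display a phantom record
#'
#' Renders the grayscale image with the lesion mask outline and,
#' optionally, a click set overlaid.
#'
#' @param record a `usj_record`.
#' @param clicks optional `usj_clicks` to overlay (foreground blue,
#'   background red).
#' @return a ggplot.
#' @export
plot_record <- function(record, clicks = NULL) {
  H <- nrow(record$image)
  df <- expand.grid(row = seq_len(H), col = seq_len(ncol(record$image)))
  df$intensity <- as.vector(record$image)
  df$mask <- as.vector(record$mask)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mask), breaks = 0.5,
                          colour = "yellow", linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, %.1f mm", record$label,
                                  record$lesion_size_mm),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(clicks)) {
    pts <- rbind(
      if (nrow(clicks$foreground))
        data.frame(row = clicks$foreground[, 1] + 1,
                   col = clicks$foreground[, 2] + 1, polarity = "fg"),
      if (nrow(clicks$background))
        data.frame(row = clicks$background[, 1] + 1,
                   col = clicks$background[, 2] + 1, polarity = "bg"))
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$col, y = .data$row,
                               colour = .data$polarity),
      inherit.aes = FALSE, size = 2) +
      ggplot2::scale_colour_manual(values = c(fg = "deepskyblue",
                                              bg = "red"),
                                   guide = "none")
  }
  p
}

#' Tidy a ROC curve into its coordinate table
#'
#' @param x a `usj_roc`.
#' @param ... unused.
#' @return tibble with `threshold`, `sensitivity`, `specificity`.
#' @export
tidy.usj_roc <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds,
                 sensitivity = x$sensitivity,
                 specificity = 1 - x$one_minus_specificity)
}

#' One-row summary of a ROC curve
#'
#' @param x a `usj_roc`.
#' @param ... unused.
#' @return tibble with the AUROC and class counts.
#' @export
glance.usj_roc <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, n_pos = x$n_pos, n_neg = x$n_neg)
}
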