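#' Accuracy and loss curves from a training history
#'
#' @param history A `training_history` data frame from [train_model()].
#' @param what `"loss"` or `"accuracy"`.
#' @return A ggplot object.
#' @export
plot_history <- function(history, what = c("loss", "accuracy")) {
  what <- match.arg(what)
  h <- as.data.frame(history)
  if (what == "loss") {
    df <- rbind(
      data.frame(epoch = h$epoch, value = h$train_loss, series = "train"),
      data.frame(epoch = h$epoch, value = h$val_loss, series = "validation"))
    ylab <- "cross-entropy loss"
  } else {
    df <- rbind(
      data.frame(epoch = h$epoch, value = h$train_acc, series = "train"),
      data.frame(epoch = h$epoch, value = h$val_acc, series = "validation"))
    if (!is.null(h$test_acc)) {
      df <- rbind(df, data.frame(epoch = h$epoch, value = h$test_acc,
                                 series = "test"))
    }
    ylab <- "accuracy (%)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map
#'
#' @param report An `eval_report` from [evaluate()].
#' @return A ggplot object (true classes in rows, negative class first).
#' @export
plot_confusion <- function(report) {
  cm <- as.data.frame(report$confusion)
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_y_discrete(limits = rev(levels(cm$truth))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

#' Group mean +/- SEM bar chart of a per-cell measure
#'
#' @param group_stats The `group_stats` element of [compare_groups()].
#' @param measure Label for the y axis.
#' @return A ggplot object.
#' @export
plot_group_means <- function(group_stats, measure = "raw_int_den") {
  ggplot2::ggplot(group_stats,
                  ggplot2::aes(x = .data$condition, y = .data$mean,
                               fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::labs(x = NULL, y = measure, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Saliency overlay of a slice and its Grad-CAM map
#'
#' @param slice An 8-bit image matrix or `processed_slice`.
#' @param saliency A `saliency_map` from [grad_cam()].
#' @param alpha Heat-map opacity.
#' @return A ggplot object.
#' @export
plot_saliency <- function(slice, saliency, alpha = 0.5) {
  px <- if (inherits(slice, "processed_slice")) slice$pixels else slice
  d <- dim(px)
  df <- data.frame(x = rep(seq_len(d[2]), each = d[1]),
                   y = rep(seq_len(d[1]), d[2]),
                   intensity = as.vector(px),
                   saliency = as.vector(saliency$map))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_raster(
      data = df[df$saliency > 0.05, ],
      ggplot2::aes(alpha = .data$saliency), fill = "red") +
    ggplot2::scale_alpha(range = c(0, alpha), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() + ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL
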