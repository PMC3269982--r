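#' Plot a width profile
#'
#' Cortical width in millimetres against ROI column, with the profile mean
#' drawn as a dashed reference line.
#'
#' @param object An `mcw_width_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcw_width_profile
#' @export
autoplot.mcw_width_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$column, y = .data$width_mm)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = mean(object$width_mm), linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "ROI column (px)", y = "Cortical width (mm)",
      title = paste0("Cortical width profile (", attr(object, "side"), " side)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot screening metrics with their confidence intervals
#'
#' Point estimates and 95% intervals for the proportion-valued metrics
#' (the likelihood ratio lives on another scale and is omitted here).
#'
#' @param object An `mcw_metrics` tibble from [screening_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcw_metrics
#' @export
autoplot.mcw_metrics <- function(object, ...) {
  df <- dplyr::filter(object, .data$metric != "lr_plus")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high)
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Proportion", title = "Screening performance") +
    ggplot2::theme_minimal()
}

#' Overlay the medial axis and cortical margins on an ROI image
#'
#' Mirrors the audit figures of the measurement chain: the grayscale ROI
#' with the dynamic-programming trace and the reconstructed upper/lower
#' margins drawn on top.
#'
#' @param image The ROI grayscale matrix.
#' @param margins An `mcw_margins` tibble.
#' @param trace Optional `mcw_trace` tibble.
#' @return A ggplot object.
#' @export
plot_margins <- function(image, margins, trace = NULL) {
  image <- as_gray_image(image)
  df <- expand.grid(row = seq_len(nrow(image)), col = seq_len(ncol(image)))
  df$intensity <- as.vector(image)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(
      data = df,
      ggplot2::aes(x = .data$col, y = .data$row, fill = .data$intensity)
    ) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_line(
      data = margins, ggplot2::aes(x = .data$col, y = .data$upper),
      colour = "orange"
    ) +
    ggplot2::geom_line(
      data = margins, ggplot2::aes(x = .data$col, y = .data$lower),
      colour = "orange"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
  if (!is.null(trace)) {
    p <- p + ggplot2::geom_line(
      data = trace, ggplot2::aes(x = .data$col, y = .data$row),
      colour = "red", linetype = "dotted"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
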