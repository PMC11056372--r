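# ggplot2 visual summaries for pipeline results.

raster_df <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is_rgb_image(image)) {
    col <- grDevices::rgb(image[, , 1], image[, , 2], image[, , 3], maxColorValue = 255)
  } else {
    g <- image / 255
    col <- grDevices::rgb(g, g, g)
  }
  data.frame(row = rep(seq_len(h), w), col = rep(seq_len(w), each = h), fill = col)
}

#' Plot an image with segmentation outlines
#'
#' Overlays the predicted mask boundary (and optionally the ground truth) on
#' the image.
#'
#' @param image RGB array or grayscale matrix.
#' @param mask predicted binary mask.
#' @param truth optional ground-truth binary mask.
#' @return a ggplot object.
#' @export
plot_segmentation <- function(image, mask, truth = NULL) {
  df <- raster_df(image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  outline <- function(m, colour) {
    oc <- EBImage::ocontour(m)
    dplyr::bind_rows(lapply(seq_along(oc), function(k) {
      data.frame(row = oc[[k]][, 1] + 1, col = oc[[k]][, 2] + 1, grp = k)
    })) -> d
    ggplot2::geom_path(data = d, ggplot2::aes(group = .data$grp),
                       colour = colour, linewidth = 0.6)
  }
  if (any(mask == 1L)) p <- p + outline(mask, "yellow")
  if (!is.null(truth) && any(truth == 1L)) p <- p + outline(truth, "cyan")
  p
}

#' Bar chart of an evaluation metrics report
#'
#' @param object one-row metrics tibble from [compute_metrics()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object, dplyr::everything(),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$metric, -.data$value),
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$value)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::ylim(0, 1.05) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
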