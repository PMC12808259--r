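#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

image_df <- function(pixels) {
  tibble::tibble(
    row = rep(seq_len(nrow(pixels)), times = ncol(pixels)),
    col = rep(seq_len(ncol(pixels)), each = nrow(pixels)),
    intensity = as.vector(pixels)
  )
}

#' Plot a calibrated image
#'
#' @param object A [gsr_image()].
#' @param ... Unused.
#' @return A ggplot raster plot, origin at the top-left as in image viewers.
#' @method autoplot gsr_image
#' @export
autoplot.gsr_image <- function(object, ...) {
  df <- image_df(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity",
                  title = sprintf("%s / %s", object$modality, object$fabric)) +
    ggplot2::theme_minimal()
}

#' Plot detected particles over the image frame
#'
#' Detections are drawn at their centroids, sized by pixel count — the visual
#' analogue of the residue pattern the quantification summarizes.
#'
#' @param object A `gsr_quant` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gsr_quant
#' @export
autoplot.gsr_quant <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centroid_col,
                                   y = .data$centroid_row,
                                   size = .data$n_pixel)) +
    ggplot2::geom_point(alpha = 0.6, colour = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(
      x = "column (px)", y = "row (px)", size = "pixels",
      title = sprintf("%d particles, %d foreground pixels",
                      object$count, object$total_pixels)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a rating matrix as rater-wise score distributions
#'
#' @param object A [rating_matrix()].
#' @param ... Unused.
#' @return A ggplot box plot, one box per rater.
#' @method autoplot rating_matrix
#' @export
autoplot.rating_matrix <- function(object, ...) {
  df <- tibble::tibble(
    rater = rep(colnames(object), each = nrow(object)),
    score = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rater, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0.08, alpha = 0.5) +
    ggplot2::scale_y_continuous(limits = c(0, 5), breaks = 0:5) +
    ggplot2::labs(x = NULL, y = "visibility score (0-5)") +
    ggplot2::theme_minimal()
}
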