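# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @export
tidy.bland_altman <- function(x, ...) x$data

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' Bland-Altman plot
#'
#' Mean-vs-difference scatter with the bias (solid) and 95 percent limits
#' of agreement (dashed).
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference (A - B)") +
    ggplot2::theme_minimal()
}

#' @export
tidy.thickness_result <- function(x, ...) {
  out <- tibble::tibble(
    column = seq_along(x$per_column_thickness_mm),
    thickness_mm = x$per_column_thickness_mm,
    outer_row = x$boundaries$outer_row_per_col,
    inner_row = x$boundaries$inner_row_per_col)
  if (!is.null(x$boundaries_image))
    out <- dplyr::bind_cols(out, x$boundaries_image)
  out
}

#' @export
glance.thickness_result <- function(x, ...) {
  tibble::tibble(mean_thickness_mm = x$mean_thickness_mm,
                 n_columns = length(x$per_column_thickness_mm),
                 total_cost = x$boundaries$total_cost)
}

#' Per-column wall thickness profile
#'
#' @param object A `thickness_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thickness_result <- function(object, ...) {
  df <- tibble::tibble(column = seq_along(object$per_column_thickness_mm),
                       thickness_mm = object$per_column_thickness_mm)
  ggplot2::ggplot(df, ggplot2::aes(column, thickness_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$mean_thickness_mm,
                        linetype = "dashed") +
    ggplot2::labs(x = "Search-box column",
                  y = "Wall thickness (mm)") +
    ggplot2::theme_minimal()
}

#' @export
tidy.bladder_segmentation <- function(x, ...) tibble::as_tibble(x$contour)

#' @export
glance.bladder_segmentation <- function(x, ...) {
  tibble::tibble(lumen_area_px = sum(x$mask),
                 center_row = x$center$row, center_col = x$center$col,
                 total_cost = x$total_cost)
}

#' Segmentation overlay
#'
#' Grayscale image raster with the detected inner boundary.
#'
#' @param object A `bladder_segmentation`.
#' @param image Optional [bmode_image()] to draw under the contour; defaults
#'   to the image stored in the result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bladder_segmentation <- function(object, image = object$image, ...) {
  layers <- list()
  if (!is.null(image)) {
    px <- if (inherits(image, "bmode_image")) image$pixels else image
    df <- tibble::tibble(x = as.vector(col(px)), y = as.vector(row(px)),
                         value = as.vector(px))
    layers <- c(layers, list(
      ggplot2::geom_raster(data = df,
                           ggplot2::aes(x = x, y = y, fill = value)),
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none")))
  }
  ggplot2::ggplot() + layers +
    ggplot2::geom_path(data = tibble::as_tibble(object$contour),
                       ggplot2::aes(x = x_px, y = y_px), colour = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "depth (px)") +
    ggplot2::theme_minimal()
}
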