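#' Parameters of the single-line boundary dynamic program
#'
#' @param delta_max Largest allowed row change between consecutive columns
#'   (default 3).
#' @param gamma Soft step penalty: a step of size `|delta|` multiplies the
#'   node cost by `1 + |delta|/gamma`; the default 20 makes each unit step a
#'   5 percent increase.
#' @param closed Whether the path must close on itself (seam gap at most
#'   `delta_max`); default `TRUE` for the 360-degree sac boundary.
#' @return An object of class `dp_params`.
#' @export
dp_params <- function(delta_max = 3, gamma = 20, closed = TRUE) {
  stopifnot(delta_max >= 0, gamma > 0)
  structure(list(delta_max = as.integer(delta_max), gamma = gamma,
                 closed = isTRUE(closed)), class = "dp_params")
}

check_cost_matrix <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) < 1 || ncol(cost) < 1)
    stop_detrusor("cost must be a non-empty numeric matrix")
  if (any(!is.finite(cost)) || any(cost < 0))
    stop_detrusor("cost values must be finite and nonnegative")
}

#' Minimal-cost open path across a cost matrix
#'
#' Finds the path `h_1..h_W` (one row per column) minimising the cumulative
#' cost `sum_w C(h_w, w) * (1 + |h_w - h_(w-1)|/gamma)` subject to
#' `|h_w - h_(w-1)| <= delta_max`, by forward recurrence and backtracking.
#' The first column carries no step penalty. The optimum is global for this
#' objective; ties prefer smaller steps, then the smaller previous row.
#'
#' @param cost Numeric matrix, rows = candidate boundary locations, columns
#'   = sequential positions (e.g. angle).
#' @param params A [dp_params()].
#' @return An object of class `dp_path`: `row_per_column` (1-based),
#'   `total_cost`.
#' @export
dp_optimal_path <- function(cost, params = dp_params(closed = FALSE)) {
  check_cost_matrix(cost)
  r <- .dp_open_cpp(cost, params$delta_max, params$gamma)
  structure(list(row_per_column = r$path + 1L, total_cost = r$cost),
            class = "dp_path")
}

#' Minimal-cost closed contour across a cost matrix
#'
#' As [dp_optimal_path()] but additionally enforces the seam constraint
#' `|h_1 - h_W| <= delta_max` so the path is a closed contour when columns
#' are angles. Closure is exact: the open problem is solved once per
#' candidate start row with the final column restricted to the seam window,
#' and the feasible minimum kept.
#'
#' @inheritParams dp_optimal_path
#' @return An object of class `dp_path`.
#' @export
dp_closed_contour <- function(cost, params = dp_params()) {
  check_cost_matrix(cost)
  r <- .dp_closed_cpp(cost, params$delta_max, params$gamma)
  structure(list(row_per_column = r$path + 1L, total_cost = r$cost),
            class = "dp_path")
}

#' Segment the bladder sac by polar dynamic programming
#'
#' Full sac pipeline: rough centre detection from the axial intensity
#' profile, signed outward radial gradient, 360-ray polar resampling out to
#' the maximum possible bladder radius, cost inversion, closed minimal-cost
#' contour search, and back-projection to image coordinates.
#'
#' @param img A [bmode_image()].
#' @param params A [dp_params()].
#' @param smooth_sigma_px Gradient pre-smoothing sigma (default 1 px).
#' @param radial_step_mm Polar radial step; defaults to one pixel spacing.
#' @param rb_variant Maximum-radius formula variant, see [max_ray_length()].
#' @return An object of class `bladder_segmentation`: `contour` (closed
#'   inner boundary), `mask` (filled lumen), `center`, `polar` (inverted
#'   cost field), `path`, `params`.
#' @export
segment_bladder_dp <- function(img, params = dp_params(),
                               smooth_sigma_px = 1,
                               radial_step_mm = img$pixel_spacing_mm,
                               rb_variant = "tan") {
  stopifnot(inherits(img, "bmode_image"))
  center <- detect_center(img)
  rb <- max_ray_length(center, img$probe, variant = rb_variant)
  grad <- radial_gradient(img, center, smooth_sigma_px)
  polar <- resample_polar(grad, center, rb, radial_step_mm,
                          img$pixel_spacing_mm, img$probe)
  polar <- invert_costs(polar)
  fit <- dp_closed_contour(t(polar$values), params)
  contour <- contour_to_cartesian(fit$row_per_column, polar)
  mask <- contour_mask(contour, dim(img$pixels), polar$center)
  structure(list(contour = contour, mask = mask, center = center,
                 polar = polar, path = fit$row_per_column,
                 total_cost = fit$total_cost, params = params, image = img),
            class = "bladder_segmentation")
}

#' @export
print.bladder_segmentation <- function(x, ...) {
  cat(sprintf("<bladder_segmentation> centre (%d, %d), lumen area %d px\n",
              x$center$row, x$center$col, sum(x$mask)))
  invisible(x)
}
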