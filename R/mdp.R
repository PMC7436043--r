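#' Parameters of the dual parallel-line wall tracker
#'
#' Controls the multidimensional dynamic program that tracks the outer and
#' inner anterior wall boundaries jointly. A per-column move of a line by
#' `delta` pixels multiplies the node cost by `(1 + alpha)^|delta|` (20
#' percent per pixel at the default 0.2), and a change `dd` of the line
#' separation adds a factor `1 + alpha3 * |dd|`. The separation is kept
#' strictly between `dmin_mm` and `dmax_mm` (1 and 7 mm by default, the
#' adult bladder wall thickness range).
#'
#' @param delta1,delta2 Largest per-column step of the outer / inner line in
#'   pixels (defaults 1).
#' @param alpha1,alpha2 Step penalties of the outer / inner line (defaults
#'   0.2).
#' @param alpha3 Separation-change (parallelism) penalty (default 0.2).
#' @param dmin_mm,dmax_mm Strict bounds on the wall thickness in mm
#'   (defaults 1 and 7).
#' @param box_above_mm,box_below_mm,box_width_mm Search-box extent: depth
#'   range above / below the mean anterior boundary position and lateral
#'   width (defaults 8, 6 and 6 mm).
#' @return An object of class `mdp_params`.
#' @export
mdp_params <- function(delta1 = 1, delta2 = 1, alpha1 = 0.2, alpha2 = 0.2,
                       alpha3 = 0.2, dmin_mm = 1, dmax_mm = 7,
                       box_above_mm = 8, box_below_mm = 6, box_width_mm = 6) {
  stopifnot(delta1 >= 1, delta2 >= 1, alpha1 >= 0, alpha2 >= 0, alpha3 >= 0,
            dmin_mm > 0, dmin_mm < dmax_mm,
            box_above_mm > 0, box_below_mm > 0, box_width_mm > 0)
  structure(list(delta1 = as.integer(delta1), delta2 = as.integer(delta2),
                 alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 dmin_mm = dmin_mm, dmax_mm = dmax_mm,
                 box_above_mm = box_above_mm, box_below_mm = box_below_mm,
                 box_width_mm = box_width_mm), class = "mdp_params")
}

# Integer pixel separations d with dmin < d*spacing < dmax (strict bounds).
d_bounds_px <- function(params, spacing_mm) {
  dmin_px <- floor(params$dmin_mm / spacing_mm + 1e-9) + 1L
  dmax_px <- ceiling(params$dmax_mm / spacing_mm - 1e-9) - 1L
  if (dmin_px > dmax_px)
    stop_detrusor("no integer separation satisfies dmin < d < dmax at this spacing")
  c(dmin_px, dmax_px)
}

#' Crop the anterior-wall search region around the sac contour
#'
#' Centres a box on the mid-top of the inner boundary: the horizontal
#' midpoint of the contour sets the column window (`box_width_mm` wide), the
#' mean depth of the anterior (shallow-side) contour points inside that
#' window sets the row reference, and the crop spans `box_above_mm` above to
#' `box_below_mm` below it. A box exceeding the image is clipped with a
#' warning.
#'
#' @param img A [bmode_image()].
#' @param inner_contour A `contour` (tibble with `x_px`, `y_px`).
#' @param params An [mdp_params()].
#' @return An object of class `wall_search_region`: `crop` (intensity
#'   matrix), `row_offset_px`, `col_offset_px` (0-based offsets back to the
#'   image), `pixel_spacing_mm`.
#' @export
crop_search_region <- function(img, inner_contour, params = mdp_params()) {
  stopifnot(inherits(img, "bmode_image"), nrow(inner_contour) > 1)
  sp <- img$pixel_spacing_mm
  mid_x <- (min(inner_contour$x_px) + max(inner_contour$x_px)) / 2
  half_w_px <- params$box_width_mm / 2 / sp
  in_win <- abs(inner_contour$x_px - mid_x) <= half_w_px
  anterior <- inner_contour$y_px < mean(inner_contour$y_px)
  pts <- inner_contour$y_px[in_win & anterior]
  if (!length(pts))
    stop_detrusor("no anterior contour points fall inside the search window")
  ybar <- mean(pts)
  n_rows <- round((params$box_above_mm + params$box_below_mm) / sp)
  n_cols <- round(params$box_width_mm / sp)
  row0 <- round(ybar - params$box_above_mm / sp)
  col0 <- round(mid_x - half_w_px)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  if (col0 < 1 || col0 + n_cols - 1 > w) {
    if (col0 + n_cols - 1 < 1 || col0 > w)
      stop_detrusor("search window lies entirely outside the image")
    warning("wall search box exceeds image laterally; clipping")
    col0 <- min(max(col0, 1), w - n_cols + 1)
  }
  if (row0 < 1 || row0 + n_rows - 1 > h) {
    warning("wall search box exceeds image vertically; clipping")
    row0 <- min(max(row0, 1), h - n_rows + 1)
  }
  crop <- img$pixels[row0:(row0 + n_rows - 1), col0:(col0 + n_cols - 1),
                     drop = FALSE]
  structure(list(crop = crop, row_offset_px = row0 - 1L,
                 col_offset_px = col0 - 1L, pixel_spacing_mm = sp),
            class = "wall_search_region")
}

#' Node cost fields for the dual-line tracker
#'
#' Computes the smoothed depth-direction gradient of the cropped search
#' field and its inversion, both shifted to be nonnegative. The outer
#' (tissue-to-wall, rising) boundary is cheap under the inverted gradient;
#' the inner (wall-to-lumen, falling) boundary is cheap under the gradient
#' itself.
#'
#' @param region A [crop_search_region()] result.
#' @param smooth_sigma_px Gaussian smoothing sigma (default 1 px).
#' @return A list with matrices `g` (shifted signed gradient) and `g_inv`
#'   (`max(g) - g`), both crop-shaped and nonnegative.
#' @export
wall_node_costs <- function(region, smooth_sigma_px = 1) {
  crop <- region$crop
  if (!length(crop)) stop_detrusor("empty crop")
  sm <- gauss_blur(crop, smooth_sigma_px)
  nr <- nrow(sm)
  g <- matrix(0, nr, ncol(sm))
  if (nr > 2) g[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  list(g = g - min(g), g_inv = max(g) - g)
}

#' Jointly track the two parallel wall boundaries
#'
#' Multidimensional dynamic program over the joint state (outer row, inner
#' row) per crop column. The node cost is `g_inv(outer) + g(inner)`;
#' transitions multiply it by the step and parallelism penalties of
#' [mdp_params()]. The state space is restricted to separations strictly
#' between `dmin_mm` and `dmax_mm`; the optimum is exact over that space.
#' Ties prefer the smaller outer row, then the smaller separation.
#'
#' @param g,g_inv Cost fields from [wall_node_costs()].
#' @param params An [mdp_params()].
#' @param spacing_mm Pixel spacing of the crop in mm.
#' @return An object of class `wall_boundaries`: `outer_row_per_col`,
#'   `inner_row_per_col` (1-based crop rows), `total_cost`, `spacing_mm`.
#' @export
mdp_dual_path <- function(g, g_inv, params = mdp_params(), spacing_mm = 0.2) {
  stopifnot(is.matrix(g), is.matrix(g_inv), all(dim(g) == dim(g_inv)))
  if (any(g < 0) || any(g_inv < 0))
    stop_detrusor("cost fields must be nonnegative")
  db <- d_bounds_px(params, spacing_mm)
  if (nrow(g) <= db[1])
    stop_detrusor("crop too short for the minimum wall separation")
  r <- .mdp_dual_cpp(g_inv, g, params$delta1, params$delta2,
                     params$alpha1, params$alpha2, params$alpha3,
                     db[1], db[2])
  structure(list(outer_row_per_col = r$outer + 1L,
                 inner_row_per_col = r$inner + 1L,
                 total_cost = r$cost, spacing_mm = spacing_mm),
            class = "wall_boundaries")
}

#' Convert dual-line boundaries to a wall thickness
#'
#' @param boundaries A [mdp_dual_path()] result.
#' @param spacing_mm Pixel spacing in mm (defaults to the value stored in
#'   `boundaries`).
#' @return An object of class `thickness_result` with `mean_thickness_mm`,
#'   `per_column_thickness_mm` and the boundaries.
#' @export
measure_thickness <- function(boundaries, spacing_mm = boundaries$spacing_mm) {
  sep <- boundaries$inner_row_per_col - boundaries$outer_row_per_col
  if (any(sep <= 0))
    stop_detrusor("inner boundary must lie below the outer boundary")
  per_col <- sep * spacing_mm
  structure(list(mean_thickness_mm = mean(per_col),
                 per_column_thickness_mm = per_col,
                 boundaries = boundaries, spacing_mm = spacing_mm),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("<thickness_result> mean wall thickness %.2f mm over %d columns\n",
              x$mean_thickness_mm, length(x$per_column_thickness_mm)))
  invisible(x)
}

#' Measure the anterior wall thickness from an image and sac contour
#'
#' Composes [crop_search_region()], [wall_node_costs()], [mdp_dual_path()]
#' and [measure_thickness()]; boundary rows are also mapped back to
#' full-image coordinates.
#'
#' @param img A [bmode_image()].
#' @param inner_contour The sac inner boundary (`contour`), e.g. from
#'   [segment_bladder_dp()].
#' @param params An [mdp_params()].
#' @param smooth_sigma_px Gradient smoothing sigma (default 1 px).
#' @return A `thickness_result`; `$boundaries_image` holds a tibble with
#'   full-image `col_px`, `outer_row_px`, `inner_row_px`.
#' @export
measure_wall_from_image <- function(img, inner_contour, params = mdp_params(),
                                    smooth_sigma_px = 1) {
  region <- crop_search_region(img, inner_contour, params)
  costs <- wall_node_costs(region, smooth_sigma_px)
  bounds <- mdp_dual_path(costs$g, costs$g_inv, params,
                          region$pixel_spacing_mm)
  res <- measure_thickness(bounds)
  res$boundaries_image <- tibble::tibble(
    col_px = region$col_offset_px + seq_along(bounds$outer_row_per_col),
    outer_row_px = region$row_offset_px + bounds$outer_row_per_col,
    inner_row_px = region$row_offset_px + bounds$inner_row_per_col)
  res$region <- region
  res
}
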