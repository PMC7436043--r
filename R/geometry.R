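#' Probe geometry for a curved-array sector image
#'
#' Describes the transducer footprint used to bound the polar resampling:
#' the physical probe width (the sector width at zero depth), the angular
#' field of view of the sector, and the image column of the sector apex.
#'
#' @param probe_width_mm Probe footprint width in mm (sector width at the
#'   skin line). Default 30 mm.
#' @param fov_deg Angular field of view of the sector in degrees, in
#'   (0, 180). Default 60.
#' @param apex_column_px Image column (1-based) of the sector apex / probe
#'   axis; `NULL` means the horizontal image centre.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(probe_width_mm = 30, fov_deg = 60,
                           apex_column_px = NULL) {
  stopifnot(probe_width_mm > 0, fov_deg > 0, fov_deg < 180)
  structure(list(probe_width_mm = probe_width_mm, fov_deg = fov_deg,
                 apex_column_px = apex_column_px),
            class = "probe_geometry")
}

#' B-mode image container
#'
#' A 2D grayscale echo-intensity grid (rows = depth, columns = lateral
#' position) with the physical pixel spacing and probe geometry attached.
#' Intensities are on the displayed 0-255 gray scale.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\].
#' @param pixel_spacing_mm Physical size of one pixel in mm (isotropic).
#' @param probe A [probe_geometry()].
#' @return An object of class `bmode_image`.
#' @export
bmode_image <- function(pixels, pixel_spacing_mm = 0.2,
                        probe = probe_geometry()) {
  stopifnot(is.matrix(pixels), nrow(pixels) > 0, ncol(pixels) > 0,
            pixel_spacing_mm > 0)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_detrusor("pixel intensities must lie in [0, 255]")
  if (is.null(probe$apex_column_px))
    probe$apex_column_px <- round(ncol(pixels) / 2)
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
                 probe = probe),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d px @ %.3g mm/px (probe %g mm, fov %g deg)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing_mm,
              x$probe$probe_width_mm, x$probe$fov_deg))
  invisible(x)
}

# Logical mask of pixels inside the imaged sector (apex at row 1; the sector
# half-width at depth z is probe_width/2 + z * tan(fov/2)).
sector_mask <- function(height, width, pixel_spacing_mm, probe) {
  z <- ((seq_len(height) - 1) * pixel_spacing_mm)
  half_w <- probe$probe_width_mm / 2 + z * tan(probe$fov_deg / 2 * pi / 180)
  lat <- abs(seq_len(width) - probe$apex_column_px) * pixel_spacing_mm
  outer(half_w, lat, `>=`)
}

#' Rough bladder centre from the axial intensity profile
#'
#' Averages a 15-column band (about 3 mm) centred on the probe axis into a
#' one-dimensional depth profile, fits a 4th-degree polynomial, and takes the
#' two interior local maxima of the fit as the anterior and posterior wall
#' depths. The rough centre point is the midpoint of the two maxima on the
#' probe axis.
#'
#' The quartic is fitted over the echogenic depth range only: leading and
#' trailing rows below `tail_floor` times the profile maximum (the hazy
#' near field and the attenuated far field, which carry no wall signal but
#' would otherwise dominate the least-squares fit) are excluded.
#'
#' @param img A [bmode_image()].
#' @param band_px Width of the averaged column band in pixels (default 15).
#' @param tail_floor Fraction of the profile maximum below which leading /
#'   trailing rows are excluded from the fit (default 0.15).
#' @return An object of class `center_estimate` with fields `row`, `col`,
#'   `depth_mm` and `peaks_px` (anterior, posterior).
#' @export
detect_center <- function(img, band_px = 15, tail_floor = 0.15) {
  stopifnot(inherits(img, "bmode_image"))
  px <- img$pixels
  apex <- img$probe$apex_column_px
  half <- band_px %/% 2
  cols <- (apex - half):(apex + half)
  if (min(cols) < 1 || max(cols) > ncol(px))
    stop_detrusor("image too narrow for the centre-detection band")
  profile <- rowMeans(px[, cols, drop = FALSE])
  keep <- which(profile >= tail_floor * max(profile))
  lo <- min(keep); hi <- max(keep)
  prof <- profile[lo:hi]
  if (length(prof) < 10)
    stop_center("echogenic depth range too short to fit the intensity profile")
  idx <- seq_along(prof)
  fit <- lm(prof ~ poly(idx, 4))
  xs <- seq(1, length(prof), by = 0.25)
  ys <- predict(fit, newdata = data.frame(idx = xs))
  d <- diff(ys)
  # interior local maxima of the fitted quartic (sign change + to -)
  peak_i <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  peak_i <- peak_i[peak_i > 1 & peak_i < length(xs)]
  if (length(peak_i) < 2)
    stop_center("intensity-profile polynomial has fewer than two interior maxima; cannot locate the bladder")
  peaks <- sort(xs[peak_i])[c(1, length(peak_i))] + lo - 1
  row <- round(mean(peaks))
  structure(list(row = as.integer(row), col = as.integer(apex),
                 depth_mm = (row - 1) * img$pixel_spacing_mm,
                 peaks_px = peaks),
            class = "center_estimate")
}

#' Maximum ray length for polar resampling
#'
#' The largest possible bladder radius seen from the rough centre point:
#' half the probe width plus the sector half-width gained over the centre
#' depth. The geometric form uses `tan(fov/2)`; a printed-formula variant
#' with `arctan(fov/2)` is retained behind `variant`.
#'
#' @param center A [detect_center()] result, or a centre depth in mm.
#' @param probe A [probe_geometry()].
#' @param variant `"tan"` (geometric sector half-width, default) or
#'   `"arctan"`.
#' @return Maximum ray length in mm.
#' @export
max_ray_length <- function(center, probe = probe_geometry(),
                           variant = c("tan", "arctan")) {
  variant <- match.arg(variant)
  depth <- if (inherits(center, "center_estimate")) center$depth_mm else center
  stopifnot(depth >= 0)
  half_fov <- probe$fov_deg / 2 * pi / 180
  slope <- if (variant == "tan") tan(half_fov) else atan(half_fov)
  probe$probe_width_mm / 2 + abs(depth) * slope
}

#' Signed outward radial gradient
#'
#' Gaussian-smooths the image and returns, at every pixel, the intensity
#' derivative along the outward direction from the centre (central
#' differences). On rays leaving the centre, a dark-to-bright (lumen to
#' wall) transition is a positive peak at every angle, so the inner
#' boundary forms a single ridge of one sign.
#'
#' @param img A [bmode_image()] or plain intensity matrix.
#' @param center A `center_estimate` (or list with `row`, `col`).
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels (default 1).
#' @return Numeric matrix of signed gradient values (per pixel, per-pixel
#'   units of intensity).
#' @export
radial_gradient <- function(img, center, smooth_sigma_px = 1) {
  px <- if (inherits(img, "bmode_image")) img$pixels else img
  sm <- gauss_blur(px, smooth_sigma_px)
  nr <- nrow(sm); nc <- ncol(sm)
  gy <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  gx <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  dy <- row(sm) - center$row
  dx <- col(sm) - center$col
  dist <- sqrt(dy^2 + dx^2)
  g <- (gy * dy + gx * dx) / pmax(dist, .Machine$double.eps)
  g[dist == 0] <- 0
  g
}

#' Resample a gradient image along 360 polar rays
#'
#' Casts 360 rays (1-degree increment) from the centre and samples the
#' gradient by bilinear interpolation every `radial_step_mm` out to the
#' maximum radius. Angle 0 points toward increasing depth (posterior) and
#' angles increase toward positive lateral x. Samples falling outside the
#' image or the imaged sector are flagged and receive the maximum cost when
#' the field is inverted, so the boundary search avoids them.
#'
#' @param gradient Numeric matrix (e.g. from [radial_gradient()]).
#' @param center A `center_estimate`.
#' @param max_radius_mm Maximum ray length in mm (e.g. [max_ray_length()]).
#' @param radial_step_mm Radial sampling step in mm; defaults to one pixel.
#' @param pixel_spacing_mm Pixel spacing of `gradient` in mm.
#' @param probe A [probe_geometry()] used for the sector validity mask;
#'   `NULL` skips the sector test.
#' @return An object of class `polar_cost`: a 360 x Nr matrix `values`
#'   (rows = angle 0..359 deg, columns = radial index), with `valid` flags
#'   and the resampling geometry attached.
#' @export
resample_polar <- function(gradient, center, max_radius_mm,
                           radial_step_mm = pixel_spacing_mm,
                           pixel_spacing_mm = 0.2, probe = NULL) {
  stopifnot(max_radius_mm > 0, radial_step_mm > 0)
  nr <- nrow(gradient); nc <- ncol(gradient)
  if (center$row < 1 || center$row > nr || center$col < 1 || center$col > nc)
    stop_detrusor("centre falls outside the image")
  n_rad <- max(1L, as.integer(ceiling(max_radius_mm / radial_step_mm)))
  theta <- (0:359) * pi / 180
  r_mm <- (seq_len(n_rad)) * radial_step_mm
  r_px <- r_mm / pixel_spacing_mm
  rows <- center$row + outer(cos(theta), r_px)   # 360 x Nr
  cols <- center$col + outer(sin(theta), r_px)
  vals <- bilinear_at(gradient, as.vector(rows), as.vector(cols))
  valid <- !is.na(vals)
  if (!is.null(probe)) {
    z_mm <- (as.vector(rows) - 1) * pixel_spacing_mm
    lat_mm <- abs(as.vector(cols) - probe$apex_column_px) * pixel_spacing_mm
    half_w <- probe$probe_width_mm / 2 +
      pmax(z_mm, 0) * tan(probe$fov_deg / 2 * pi / 180)
    valid <- valid & z_mm >= 0 & lat_mm <= half_w
  }
  vals[!valid] <- 0
  structure(list(values = matrix(vals, 360, n_rad),
                 valid = matrix(valid, 360, n_rad),
                 radial_step_mm = radial_step_mm,
                 pixel_spacing_mm = pixel_spacing_mm,
                 center = center, max_radius_mm = max_radius_mm),
            class = "polar_cost")
}

#' Invert a cost field
#'
#' Subtracts every value from the field maximum so that strong (high
#' gradient) responses become low-cost, as required by a minimal-cost path
#' search. Flagged out-of-image / out-of-sector samples are assigned the
#' maximum resulting cost.
#'
#' @param polar A `polar_cost` object or plain numeric matrix.
#' @return Same type as the input with values `max - v` (minimum 0).
#' @export
invert_costs <- function(polar) {
  if (is.matrix(polar)) return(max(polar) - polar)
  stopifnot(inherits(polar, "polar_cost"))
  v <- polar$values
  ok <- polar$valid
  m <- max(v[ok])
  out <- m - v
  out[!ok] <- max(out[ok])
  polar$values <- out
  polar
}

#' Transform a per-angle radial path back to image coordinates
#'
#' Maps radial indices (one per degree) found in the polar cost image back
#' to (x, y) pixel coordinates around the centre, producing a closed contour.
#'
#' @param path Numeric vector of length 360: radial sample index per angle.
#' @param polar The `polar_cost` the path was found in.
#' @return A tibble of class `contour` with columns `angle_deg`, `x_px`,
#'   `y_px`; the centre and closure flag are attached as attributes.
#' @export
contour_to_cartesian <- function(path, polar) {
  stopifnot(inherits(polar, "polar_cost"), length(path) == 360)
  theta <- (0:359) * pi / 180
  r_px <- path * polar$radial_step_mm / polar$pixel_spacing_mm
  out <- tibble::tibble(angle_deg = 0:359,
                        x_px = polar$center$col + r_px * sin(theta),
                        y_px = polar$center$row + r_px * cos(theta))
  structure(out, class = c("contour", class(out)),
            closed = TRUE, center = polar$center)
}

#' Rasterize a star-shaped closed contour into a filled binary mask
#'
#' Fills the region enclosed by a contour that is star-shaped about its
#' centre (every ray from the centre crosses the contour once), by comparing
#' each pixel's radius with the angularly interpolated contour radius.
#'
#' @param contour A `contour` (tibble with `x_px`, `y_px`), angularly
#'   ordered around `center`.
#' @param dim Image dimensions `c(height, width)`.
#' @param center Optional list with `row`, `col`; defaults to the contour's
#'   centre attribute or centroid.
#' @return Logical matrix of the enclosed region.
#' @export
contour_mask <- function(contour, dim, center = NULL) {
  if (is.null(center)) center <- attr(contour, "center")
  if (is.null(center))
    center <- list(row = mean(contour$y_px), col = mean(contour$x_px))
  dyc <- contour$y_px - center$row
  dxc <- contour$x_px - center$col
  th <- (atan2(dxc, dyc) * 180 / pi) %% 360
  r <- sqrt(dyc^2 + dxc^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  # pad for wraparound interpolation
  th_ext <- c(th[length(th)] - 360, th, th[1] + 360)
  r_ext <- c(r[length(r)], r, r[1])
  dy <- row(matrix(0, dim[1], dim[2])) - center$row
  dx <- col(matrix(0, dim[1], dim[2])) - center$col
  th_pix <- (atan2(dx, dy) * 180 / pi) %% 360
  r_pix <- sqrt(dy^2 + dx^2)
  rb <- matrix(stats::approx(th_ext, r_ext, xout = as.vector(th_pix),
                             ties = mean)$y,
               dim[1], dim[2])
  r_pix <= rb & rb > 0
}
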