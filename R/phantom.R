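#' Specification of a synthetic sector phantom
#'
#' Describes a B-mode-like test image: a curved-array sector (apex at the
#' top) containing an anechoic elliptical bladder lumen surrounded by a
#' bright wall of known constant thickness, embedded in moderate-intensity
#' tissue, with multiplicative speckle, Gaussian blur, optional angular
#' wall dropout and bright clutter blobs.
#'
#' @param image_height_px,image_width_px Image size in pixels (defaults
#'   880 x 1068).
#' @param pixel_spacing_mm Pixel spacing in mm (default 0.2).
#' @param probe_width_mm,fov_deg Sector geometry (defaults 30 mm, 60 deg).
#' @param apex_column_px Apex column; `NULL` = image centre.
#' @param lumen_center_mm Named or plain pair `(depth, lateral)` of the lumen
#'   centre in mm; lateral is measured from the probe axis.
#' @param lumen_semi_axes_mm Pair `(a, b)`: depth and lateral semi-axes in mm.
#' @param wall_thickness_mm Wall thickness in mm, within \[1, 7\].
#' @param lumen_intensity,wall_intensity,tissue_intensity Gray levels of the
#'   anechoic lumen (near 0), bright wall and surrounding tissue; must
#'   satisfy lumen < tissue < wall.
#' @param speckle_scale Strength of the multiplicative Rayleigh speckle in
#'   \[0, 1\]; 0 disables noise. Default 0.6.
#' @param blur_sigma_px Gaussian blur sigma (pixels) applied after speckle.
#' @param near_field_floor,near_field_depth_mm Near-field haze: brightness
#'   ramps from `near_field_floor` at the probe face to full over
#'   `near_field_depth_mm` (defaults 0.35 and 20 mm), emulating the
#'   unfocused near zone of a curved array.
#' @param attenuation_start_mm,attenuation_length_mm,attenuation_floor
#'   Far-field attenuation as a function of the tissue-only path (the fluid
#'   lumen attenuates negligibly, which produces the classic posterior
#'   acoustic enhancement behind the bladder): full brightness up to
#'   `attenuation_start_mm` of tissue path, then a linear roll-off to
#'   `attenuation_floor` over `attenuation_length_mm` (defaults 35 mm,
#'   30 mm, 0.12).
#' @param fat_band_mm,fat_band_gain Echogenic prevesical fat/fascia band
#'   directly above the anterior wall: thickness in mm and brightness gain
#'   over tissue (defaults 5 mm and 1.5).
#' @param dropout_arcs List of `c(start_deg, end_deg)` angular ranges (angle
#'   0 points posterior/down, increasing toward positive lateral x) where the
#'   wall brightness is removed, emulating boundary dropout.
#' @param clutter_blob_count Number of bright Gaussian clutter blobs placed
#'   in the tissue.
#' @param seed Default RNG seed used by [generate_phantom()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height_px = 880, image_width_px = 1068,
                         pixel_spacing_mm = 0.2, probe_width_mm = 30,
                         fov_deg = 60, apex_column_px = NULL,
                         lumen_center_mm = c(depth = 70, lateral = 0),
                         lumen_semi_axes_mm = c(a = 30, b = 35),
                         wall_thickness_mm = 2.6,
                         lumen_intensity = 10, wall_intensity = 210,
                         tissue_intensity = 90,
                         speckle_scale = 0.6, blur_sigma_px = 1.5,
                         near_field_floor = 0.35, near_field_depth_mm = 20,
                         attenuation_start_mm = 35,
                         attenuation_length_mm = 30, attenuation_floor = 0.12,
                         fat_band_mm = 5, fat_band_gain = 1.5,
                         dropout_arcs = list(), clutter_blob_count = 0,
                         seed = 1L) {
  if (is.null(apex_column_px)) apex_column_px <- round(image_width_px / 2)
  spec <- structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_spacing_mm = pixel_spacing_mm,
    probe_width_mm = probe_width_mm, fov_deg = fov_deg,
    apex_column_px = as.integer(apex_column_px),
    lumen_center_mm = unname(lumen_center_mm),
    lumen_semi_axes_mm = unname(lumen_semi_axes_mm),
    wall_thickness_mm = wall_thickness_mm,
    lumen_intensity = lumen_intensity, wall_intensity = wall_intensity,
    tissue_intensity = tissue_intensity,
    speckle_scale = speckle_scale, blur_sigma_px = blur_sigma_px,
    near_field_floor = near_field_floor,
    near_field_depth_mm = near_field_depth_mm,
    attenuation_start_mm = attenuation_start_mm,
    attenuation_length_mm = attenuation_length_mm,
    attenuation_floor = attenuation_floor,
    fat_band_mm = fat_band_mm, fat_band_gain = fat_band_gain,
    dropout_arcs = dropout_arcs,
    clutter_blob_count = as.integer(clutter_blob_count),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (wall_thickness_mm < 1 || wall_thickness_mm > 7)
      stop_detrusor("wall_thickness_mm must lie in [1, 7] mm")
    if (!(lumen_intensity < tissue_intensity && tissue_intensity < wall_intensity))
      stop_detrusor("intensities must satisfy lumen < tissue < wall")
    if (speckle_scale < 0 || blur_sigma_px < 0 || clutter_blob_count < 0)
      stop_detrusor("speckle_scale, blur_sigma_px, clutter_blob_count must be nonnegative")
  })
  # lumen ellipse plus wall must fit inside the imaged sector
  th <- (0:359) * pi / 180
  a <- spec$lumen_semi_axes_mm[1]; b <- spec$lumen_semi_axes_mm[2]
  t <- spec$wall_thickness_mm
  z0 <- spec$lumen_center_mm[1]; x0 <- spec$lumen_center_mm[2]
  zz <- z0 + cos(th) * a      # ellipse point (depth)
  xx <- x0 + sin(th) * b      # ellipse point (lateral)
  # outward unit normal of ((x-x0)/b)^2 + ((z-z0)/a)^2 = 1 at parameter th
  nrm <- sqrt((sin(th) / b)^2 + (cos(th) / a)^2)
  nx <- (sin(th) / b) / nrm; nz <- (cos(th) / a) / nrm
  zo <- zz + t * nz; xo <- xx + t * nx
  depth_max <- (spec$image_height_px - 1) * spec$pixel_spacing_mm
  half_w <- spec$probe_width_mm / 2 + pmax(zo, 0) * tan(spec$fov_deg / 2 * pi / 180)
  lat <- abs(xo)
  margin <- spec$pixel_spacing_mm / 2
  if (any(zo < margin) || any(zo > depth_max - margin) || any(lat > half_w - margin))
    stop_detrusor("lumen ellipse plus wall does not fit inside the imaged sector")
  invisible(spec)
}

# Ellipse boundary (inner wall) sampled each degree; returns contour tibble
# in pixel coordinates plus the outward unit normal per point (mm frame).
ellipse_contour <- function(spec) {
  th <- (0:359) * pi / 180
  a <- spec$lumen_semi_axes_mm[1]; b <- spec$lumen_semi_axes_mm[2]
  z0 <- spec$lumen_center_mm[1]; x0 <- spec$lumen_center_mm[2]
  zz <- z0 + cos(th) * a
  xx <- x0 + sin(th) * b
  nrm <- sqrt((sin(th) / b)^2 + (cos(th) / a)^2)
  list(theta_deg = 0:359,
       z_mm = zz, x_mm = xx,
       nz = (cos(th) / a) / nrm, nx = (sin(th) / b) / nrm)
}

mm_to_row <- function(z_mm, spec) z_mm / spec$pixel_spacing_mm + 1
mm_to_col <- function(x_mm, spec) x_mm / spec$pixel_spacing_mm + spec$apex_column_px

#' Generate one synthetic phantom with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: base intensities for
#' tissue / wall / lumen, wall dropout arcs, clutter blobs, multiplicative
#' Rayleigh speckle, Gaussian blur, and zeroing outside the sector. Output is
#' quantised to the 8-bit 0-255 range and deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return An object of class `phantom_sample`: `image` ([bmode_image()]),
#'   `lumen_mask` (logical), `inner_contour` and `outer_anterior_contour`
#'   (`contour` tibbles), `true_thickness_mm`, and the `spec`.
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  h <- spec$image_height_px; w <- spec$image_width_px
  sp <- spec$pixel_spacing_mm
  z <- (row(matrix(0, h, w)) - 1) * sp
  x <- (col(matrix(0, h, w)) - spec$apex_column_px) * sp
  a <- spec$lumen_semi_axes_mm[1]; b <- spec$lumen_semi_axes_mm[2]
  z0 <- spec$lumen_center_mm[1]; x0 <- spec$lumen_center_mm[2]
  t <- spec$wall_thickness_mm

  lumen <- ((x - x0) / b)^2 + ((z - z0) / a)^2 <= 1
  dist_px <- matrix(EBImage::distmap(matrix(as.numeric(!lumen), h, w)), h, w)
  wall <- !lumen & dist_px * sp <= t
  fat <- !lumen & !wall & dist_px * sp <= t + spec$fat_band_mm & z < z0

  img <- matrix(spec$tissue_intensity, h, w)
  img[fat] <- spec$tissue_intensity * spec$fat_band_gain
  img[wall] <- spec$wall_intensity
  img[lumen] <- spec$lumen_intensity

  # wall dropout: remove wall brightness over the listed angular arcs
  if (length(spec$dropout_arcs)) {
    thp <- (atan2(x - x0, z - z0) * 180 / pi) %% 360
    for (arc in spec$dropout_arcs) {
      inarc <- if (arc[1] <= arc[2]) thp >= arc[1] & thp <= arc[2]
               else thp >= arc[1] | thp <= arc[2]
      img[wall & inarc] <- spec$lumen_intensity
    }
  }

  probe <- probe_geometry(spec$probe_width_mm, spec$fov_deg, spec$apex_column_px)
  sect <- sector_mask(h, w, sp, probe)

  # depth shading: unfocused near field, and far-field attenuation driven by
  # the tissue-only path (the anechoic lumen attenuates negligibly, which
  # yields posterior acoustic enhancement below the bladder).
  chord_half <- a * sqrt(pmax(1 - ((x - x0) / b)^2, 0))
  fluid <- pmin(pmax(z - (z0 - chord_half), 0), 2 * chord_half)
  tissue_path <- z - fluid
  shade <- pmin(1, spec$near_field_floor +
                  (1 - spec$near_field_floor) * z / spec$near_field_depth_mm) *
    pmin(1, pmax(spec$attenuation_floor,
                 1 - (1 - spec$attenuation_floor) *
                   (tissue_path - spec$attenuation_start_mm) /
                   spec$attenuation_length_mm))

  with_seed(seed, {
    if (spec$clutter_blob_count > 0) {
      placed <- 0L
      while (placed < spec$clutter_blob_count) {
        cz <- runif(1, 5, (h - 1) * sp - 5)
        cx <- runif(1, -spec$probe_width_mm, spec$probe_width_mm) +
          runif(1, -1, 1) * cz * tan(spec$fov_deg / 2 * pi / 180) / 2
        # keep clutter in tissue, clear of the wall by 2 mm
        if (((cx - x0) / (b + t + 2))^2 + ((cz - z0) / (a + t + 2))^2 <= 1) next
        rr <- round(mm_to_row(cz, spec)); cc <- round(mm_to_col(cx, spec))
        if (rr < 1 || rr > h || cc < 1 || cc > w || !sect[rr, cc]) next
        sig <- runif(1, 1.5, 4)
        amp <- runif(1, 60, 140)
        img <- img + amp * exp(-(((z - cz)^2 + (x - cx)^2) / (2 * sig^2)))
        placed <- placed + 1L
      }
    }
    img <- img * shade
    if (spec$speckle_scale > 0) {
      u <- matrix(runif(h * w), h, w)
      ray <- sqrt(-2 * log(u)) / sqrt(pi / 2)   # Rayleigh, unit mean
      img <- img * (1 + spec$speckle_scale * (ray - 1))
    }
  })
  img <- pmax(img, 0)
  img <- gauss_blur(img, spec$blur_sigma_px)
  img[!sect] <- 0
  img <- round(pmin(pmax(img, 0), 255))

  ec <- ellipse_contour(spec)
  center_px <- list(row = mm_to_row(z0, spec), col = mm_to_col(x0, spec))
  inner <- tibble::tibble(angle_deg = ec$theta_deg,
                          x_px = mm_to_col(ec$x_mm, spec),
                          y_px = mm_to_row(ec$z_mm, spec))
  inner <- structure(inner, class = c("contour", class(inner)),
                     closed = TRUE, center = center_px)
  ant <- ec$nz < 0   # outward normal points up: anterior (shallow) side
  outer_ant <- tibble::tibble(angle_deg = ec$theta_deg[ant],
                              x_px = mm_to_col(ec$x_mm[ant] + t * ec$nx[ant], spec),
                              y_px = mm_to_row(ec$z_mm[ant] + t * ec$nz[ant], spec))
  outer_ant <- structure(outer_ant, class = c("contour", class(outer_ant)),
                         closed = FALSE, center = center_px)

  structure(list(
    image = bmode_image(img, sp, probe),
    lumen_mask = lumen,
    inner_contour = inner,
    outer_anterior_contour = outer_ant,
    true_thickness_mm = t,
    spec = spec, seed = as.integer(seed)), class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d x %d px, wall %.2f mm, seed %d\n",
              nrow(x$image$pixels), ncol(x$image$pixels),
              x$true_thickness_mm, x$seed))
  invisible(x)
}

#' Generate a seeded phantom dataset with a manifest
#'
#' Draws `n` phantoms whose wall thickness, lumen semi-axes and anterior wall
#' depth are sampled uniformly from the given ranges. The lumen centre depth
#' is derived so the lumen plus wall fits the sector laterally. Subject ids
#' are assigned in consecutive blocks so subject-level cross-validation folds
#' can be formed downstream.
#'
#' @param n Number of phantoms (>= 1).
#' @param thickness_range_mm Range of wall thickness (default `c(1.5, 5)`).
#' @param semi_axes_range_mm Range both lumen semi-axes are drawn from
#'   (default `c(25, 45)`).
#' @param anterior_depth_range_mm Range of the anterior wall depth below the
#'   probe (default `c(15, 30)`).
#' @param images_per_subject Block size for subject-id assignment (default 5).
#' @param seed Master seed; per-sample seeds are drawn from it.
#' @param dir Optional directory; when given, image / mask / contour files
#'   are written there and their paths recorded in the manifest.
#' @param base_spec A [phantom_spec()] providing all remaining fields.
#' @param render Render the images (default); `FALSE` returns the manifest
#'   only, useful for inspecting the sampled conditions.
#' @return A list with `samples` (list of `phantom_sample`) and `manifest`
#'   (a tibble: sample_id, subject_id, seed, thickness_mm, geometry, paths).
#' @export
generate_dataset <- function(n, thickness_range_mm = c(1.5, 5),
                             semi_axes_range_mm = c(25, 45),
                             anterior_depth_range_mm = c(15, 30),
                             images_per_subject = 5, seed = 1,
                             dir = NULL, base_spec = phantom_spec(),
                             render = TRUE) {
  if (n < 1) stop_detrusor("n must be >= 1")
  for (rg in list(thickness_range_mm, semi_axes_range_mm, anterior_depth_range_mm))
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[1] > rg[2])
      stop_detrusor("ranges must be finite length-2 vectors with min <= max")
  half_fov <- base_spec$fov_deg / 2 * pi / 180
  draws <- with_seed(seed, {
    tibble::tibble(
      sample_id = sprintf("phantom_%03d", seq_len(n)),
      subject_id = sprintf("subject_%02d",
                           (seq_len(n) - 1) %/% images_per_subject + 1),
      seed = sample.int(.Machine$integer.max %/% 2, n),
      thickness_mm = runif(n, thickness_range_mm[1], thickness_range_mm[2]),
      depth_semi_axis_mm = runif(n, semi_axes_range_mm[1], semi_axes_range_mm[2]),
      lateral_semi_axis_mm = runif(n, semi_axes_range_mm[1], semi_axes_range_mm[2]),
      anterior_depth_mm = runif(n, anterior_depth_range_mm[1],
                                anterior_depth_range_mm[2]))
  })
  # centre depth: anterior offset plus whatever depth the sector cone needs
  # for the outer (wall) contour to fit laterally, with a 1 mm margin
  th <- (0:359) * pi / 180
  lat_need <- vapply(seq_len(n), function(i) {
    a <- draws$depth_semi_axis_mm[i]; b <- draws$lateral_semi_axis_mm[i]
    t <- draws$thickness_mm[i]
    nrm <- sqrt((sin(th) / b)^2 + (cos(th) / a)^2)
    zeta <- cos(th) * a + t * (cos(th) / a) / nrm   # outer depth offset
    xo <- sin(th) * b + t * (sin(th) / b) / nrm     # outer lateral offset
    max((abs(xo) + 1 + base_spec$pixel_spacing_mm -
           base_spec$probe_width_mm / 2) / tan(half_fov) - zeta)
  }, numeric(1))
  draws$center_depth_mm <- pmax(
    draws$anterior_depth_mm + draws$depth_semi_axis_mm + draws$thickness_mm,
    lat_need)

  samples <- if (!render) NULL else
    purrr::pmap(draws, function(sample_id, subject_id, seed,
                                         thickness_mm, depth_semi_axis_mm,
                                         lateral_semi_axis_mm,
                                         anterior_depth_mm, center_depth_mm) {
    sp <- base_spec
    sp$lumen_center_mm <- c(center_depth_mm, 0)
    sp$lumen_semi_axes_mm <- c(depth_semi_axis_mm, lateral_semi_axis_mm)
    sp$wall_thickness_mm <- thickness_mm
    sp$seed <- as.integer(seed)
    generate_phantom(sp)
  })
  manifest <- draws
  manifest$image_path <- NA_character_
  manifest$mask_path <- NA_character_
  manifest$contour_path <- NA_character_
  if (!is.null(dir) && render) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      stem <- file.path(dir, manifest$sample_id[i])
      manifest$image_path[i] <- paste0(stem, ".png")
      manifest$mask_path[i] <- paste0(stem, "_mask.png")
      manifest$contour_path[i] <- paste0(stem, "_contour.csv")
      png::writePNG(samples[[i]]$image$pixels / 255, manifest$image_path[i])
      png::writePNG(samples[[i]]$lumen_mask * 1.0, manifest$mask_path[i])
      write_contour_csv(samples[[i]]$inner_contour, manifest$contour_path[i])
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Generate one phantom under the validation imaging conditions
#'
#' Draws a single phantom whose geometry follows the validation condition
#' distribution (wall thickness uniform in 1.5-5 mm, lumen semi-axes uniform
#' in 25-45 mm, anterior wall depth uniform in 15-30 mm, default sector
#' geometry, speckle and blur), fully determined by `seed`. The centre depth
#' is derived exactly as in [generate_dataset()].
#'
#' @param seed Seed determining both the sampled geometry and the speckle.
#' @param speckle_scale,blur_sigma_px Overrides for the noise level
#'   (defaults are the [phantom_spec()] defaults).
#' @return A `phantom_sample`.
#' @export
study_phantom <- function(seed, speckle_scale = NULL, blur_sigma_px = NULL) {
  base <- phantom_spec()
  if (!is.null(speckle_scale)) base$speckle_scale <- speckle_scale
  if (!is.null(blur_sigma_px)) base$blur_sigma_px <- blur_sigma_px
  g <- with_seed(seed, list(
    t = runif(1, 1.5, 5),
    a = runif(1, 25, 45), b = runif(1, 25, 45),
    ant = runif(1, 15, 30)))
  th <- (0:359) * pi / 180
  nrm <- sqrt((sin(th) / g$b)^2 + (cos(th) / g$a)^2)
  zeta <- cos(th) * g$a + g$t * (cos(th) / g$a) / nrm
  xo <- sin(th) * g$b + g$t * (sin(th) / g$b) / nrm
  half_fov <- base$fov_deg / 2 * pi / 180
  lat_need <- max((abs(xo) + 1 + base$pixel_spacing_mm -
                     base$probe_width_mm / 2) / tan(half_fov) - zeta)
  base$lumen_center_mm <- c(max(g$ant + g$a + g$t, lat_need), 0)
  base$lumen_semi_axes_mm <- c(g$a, g$b)
  base$wall_thickness_mm <- g$t
  base$seed <- as.integer(seed)
  generate_phantom(base)
}
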