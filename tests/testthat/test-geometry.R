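# Image model, centre detection, polar resampling.

profile_image <- function(profile, width = 31) {
  bmode_image(matrix(rep(profile, width), length(profile), width),
              pixel_spacing_mm = 0.2,
              probe = probe_geometry(fov_deg = 179, apex_column_px =
                                       round(width / 2)))
}

test_that("centre detection finds the midpoint of a two-bump profile", {
  z <- seq_len(600)
  prof <- 50 + 150 * exp(-(z - 100)^2 / (2 * 40^2)) +
    150 * exp(-(z - 500)^2 / (2 * 40^2))
  # oracle: dense grid search over the fitted quartic
  fit <- lm(prof ~ poly(z, 4))
  xs <- seq(1, 600, by = 0.1)
  ys <- predict(fit, newdata = data.frame(z = xs))
  d <- diff(ys)
  pk <- xs[which(d[-length(d)] > 0 & d[-1] <= 0) + 1]
  expect_length(pk, 2)
  oracle_mid <- mean(pk)

  ctr <- detect_center(profile_image(prof))
  expect_lt(abs(ctr$row - oracle_mid), 1)
  expect_lt(abs(ctr$row - 300), 10)
  expect_lt(ctr$peaks_px[1], ctr$row)
  expect_gt(ctr$peaks_px[2], ctr$row)
})

test_that("centre detection is symmetric and offset-invariant", {
  z <- seq_len(600)
  prof <- 40 + 120 * exp(-(z - 150)^2 / (2 * 35^2)) +
    120 * exp(-(z - 450)^2 / (2 * 35^2))
  ctr <- detect_center(profile_image(prof))
  expect_equal(ctr$row, 300L)
  ctr2 <- detect_center(profile_image(prof + 30))
  expect_equal(ctr2$row, ctr$row)
})

test_that("monotone or blank profiles raise a centre-detection error", {
  expect_error(detect_center(profile_image(seq(10, 200, length.out = 500))),
               class = "center_detection_error")
  expect_error(detect_center(profile_image(rep(0, 400) + c(100, rep(0, 399)))),
               class = "center_detection_error")
})

test_that("maximum ray length follows the sector geometry", {
  probe <- probe_geometry(probe_width_mm = 30, fov_deg = 60)
  expect_equal(max_ray_length(0, probe), 15)
  expect_equal(max_ray_length(50, probe), 15 + 50 * tan(pi / 6))
  expect_equal(max_ray_length(50, probe), 43.8675, tolerance = 1e-4)
  # printed-formula variant retains arctan
  expect_equal(max_ray_length(50, probe, variant = "arctan"),
               15 + 50 * atan(pi / 6))
  # near-zero field of view leaves only the probe half-width
  expect_equal(max_ray_length(80, probe_geometry(30, 1e-6)), 15,
               tolerance = 1e-4)
  # monotone in depth and fov
  depths <- seq(0, 100, by = 10)
  expect_true(all(diff(vapply(depths, max_ray_length, numeric(1),
                              probe = probe)) > 0))
  fovs <- seq(10, 170, by = 20)
  expect_true(all(diff(vapply(fovs, function(f)
    max_ray_length(50, probe_geometry(30, f)), numeric(1))) > 0))
})

test_that("radial gradient is signed along the outward direction", {
  ctr <- list(row = 100L, col = 100L)
  expect_lt(max(abs(radial_gradient(matrix(7, 199, 199), ctr))), 1e-10)

  # bright disc on dark background: rising edge on the way out is positive
  m <- matrix(0, 199, 199)
  d <- sqrt((row(m) - 100)^2 + (col(m) - 100)^2)
  m[d <= 40] <- 0
  m[d > 40] <- 200   # dark inside, bright outside: step at radius 40
  g <- radial_gradient(m, ctr, smooth_sigma_px = 1)
  up <- g[100 - (30:50), 100]   # along the upward ray
  expect_gt(max(up), 0)
  expect_equal((30:50)[which.max(up)], 40, tolerance = 1)

  # noise-free phantom, outward convention on the anterior midline:
  # inner boundary (lumen -> wall) positive, outer (wall -> fat) negative
  ph <- generate_phantom(small_spec(speckle_scale = 0, blur_sigma_px = 0))
  sp <- ph$spec
  ctr <- list(row = round(sp$lumen_center_mm[1] / sp$pixel_spacing_mm) + 1,
              col = sp$apex_column_px)
  g <- radial_gradient(ph$image$pixels, ctr, smooth_sigma_px = 1)
  inner_row <- round((sp$lumen_center_mm[1] - sp$lumen_semi_axes_mm[1]) /
                       sp$pixel_spacing_mm) + 1
  outer_row <- inner_row - round(sp$wall_thickness_mm / sp$pixel_spacing_mm)
  band <- function(r) g[(r - 2):(r + 2), sp$apex_column_px]
  expect_gt(max(band(inner_row)), 0)
  expect_lt(min(band(outer_row)), 0)
})

test_that("polar resampling locates a symmetric ring on every ray", {
  ctr <- structure(list(row = 150L, col = 150L, depth_mm = 29.8),
                   class = "center_estimate")
  m <- matrix(0, 299, 299)
  d <- sqrt((row(m) - 150)^2 + (col(m) - 150)^2)
  m[] <- exp(-(d - 60)^2 / 8)
  pol <- resample_polar(m, ctr, max_radius_mm = 100 * 0.2,
                        radial_step_mm = 0.2, pixel_spacing_mm = 0.2)
  peaks <- apply(pol$values, 1, which.max)
  expect_true(all(abs(peaks - 60) <= 1))

  # degenerate: max radius below one step gives a single column
  pol1 <- resample_polar(m, ctr, max_radius_mm = 0.1, radial_step_mm = 0.2,
                         pixel_spacing_mm = 0.2)
  expect_equal(ncol(pol1$values), 1L)

  # all-zero field: every ray identical
  pol0 <- resample_polar(matrix(0, 299, 299), ctr, 20, 0.2, 0.2)
  expect_true(all(pol0$values == 0))

  expect_error(resample_polar(m, list(row = -5, col = 150), 20, 0.2, 0.2),
               "outside")
})

test_that("cost inversion flips the field and zeroes the minimum", {
  expect_equal(invert_costs(matrix(c(0, 2, 5), 1)),
               matrix(c(5, 3, 0), 1))
  expect_true(all(invert_costs(matrix(4, 3, 3)) == 0))
  # double inversion restores the field up to an additive constant
  v <- matrix(runif(20, 0, 9), 4)
  expect_equal(invert_costs(invert_costs(v)), v - min(v))
})

test_that("out-of-sector polar samples receive the maximum cost", {
  ctr <- structure(list(row = 100L, col = 100L), class = "center_estimate")
  m <- matrix(runif(199 * 199), 199, 199)
  pol <- resample_polar(m, ctr, max_radius_mm = 30, radial_step_mm = 0.2,
                        pixel_spacing_mm = 0.2,
                        probe = probe_geometry(30, 60, 100L))
  inv <- invert_costs(pol)
  expect_true(any(!pol$valid))
  expect_true(all(inv$values[!pol$valid] == max(inv$values[pol$valid])))
  expect_true(all(inv$values >= 0))
})

test_that("polar paths project back to image coordinates exactly", {
  ctr <- structure(list(row = 200L, col = 220L), class = "center_estimate")
  m <- matrix(0, 450, 450)
  for (r_px in c(10, 60, 150)) {
    pol <- resample_polar(m, ctr, max_radius_mm = 200 * 0.2,
                          radial_step_mm = 0.2, pixel_spacing_mm = 0.2)
    cont <- contour_to_cartesian(rep(r_px, 360), pol)
    rad <- sqrt((cont$x_px - 220)^2 + (cont$y_px - 200)^2)
    expect_true(all(abs(rad - r_px) <= 1))
    # filled mask area close to the disc area
    msk <- contour_mask(cont, c(450, 450))
    expect_lt(abs(sum(msk) - pi * r_px^2), 0.1 * pi * r_px^2 + 12)
  }
  # degenerate zero-radius path: no enclosed pixels
  pol <- resample_polar(m, ctr, 40, 0.2, 0.2)
  cont0 <- contour_to_cartesian(rep(0, 360), pol)
  expect_equal(sum(contour_mask(cont0, c(450, 450))), 0)
})
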