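# Synthetic sector phantom generator.

test_that("a noise-free phantom renders the prescribed wall thickness", {
  spec <- phantom_spec(speckle_scale = 0, blur_sigma_px = 0,
                       wall_thickness_mm = 2.6)
  ph <- generate_phantom(spec)
  px <- ph$image$pixels
  mid <- spec$apex_column_px
  ctr_row <- round(spec$lumen_center_mm[1] / spec$pixel_spacing_mm) + 1
  # anterior wall: contiguous bright run along the midline above the lumen
  # (attenuation shades the wall slightly, so threshold between the wall and
  # the fat band brightness)
  above <- px[1:ctr_row, mid]
  wall_rows <- which(above > 170)
  expect_equal(length(wall_rows), 13)   # 2.6 mm at 0.2 mm/px
  expect_equal(max(diff(wall_rows)), 1)
})

test_that("phantom generation is deterministic per seed", {
  spec <- phantom_spec(clutter_blob_count = 2)
  a <- generate_phantom(spec, seed = 42)
  b <- generate_phantom(spec, seed = 42)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$lumen_mask, b$lumen_mask)
  c <- generate_phantom(spec, seed = 43)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("geometry that cannot fit the sector is rejected", {
  expect_error(phantom_spec(lumen_semi_axes_mm = c(150, 40)),
               "fit inside")
  expect_error(phantom_spec(lumen_center_mm = c(20, 0)), "fit inside")
  expect_error(phantom_spec(wall_thickness_mm = 0.5), "1, 7")
  expect_error(phantom_spec(tissue_intensity = 250), "lumen < tissue < wall")
})

test_that("ground-truth mask, contour and thickness are consistent", {
  ph <- generate_phantom(small_spec(speckle_scale = 0, blur_sigma_px = 0,
                                    wall_thickness_mm = 3))
  # re-derived mask from the inner contour reproduces the lumen mask
  # 1-degree contour sampling vs the exact ellipse: boundary pixels may
  # differ by interpolation, so agreement is near-perfect, not bit-exact
  m2 <- contour_mask(ph$inner_contour, dim(ph$image$pixels))
  expect_gte(dice(m2, ph$lumen_mask), 0.999)
  # anterior separation between outer and inner contours equals the wall
  # thickness within one pixel spacing
  sp <- ph$spec$pixel_spacing_mm
  io <- merge(as.data.frame(ph$inner_contour),
              as.data.frame(ph$outer_anterior_contour), by = "angle_deg")
  sep_mm <- sqrt((io$x_px.x - io$x_px.y)^2 + (io$y_px.x - io$y_px.y)^2) * sp
  expect_true(all(abs(sep_mm - 3) <= sp))
})

test_that("wall dropout arcs remove the boundary and clutter stays put", {
  spec <- small_spec(speckle_scale = 0, blur_sigma_px = 0,
                     dropout_arcs = list(c(120, 160)))
  ph <- generate_phantom(spec)
  px <- ph$image$pixels
  sp <- spec$pixel_spacing_mm
  z0 <- spec$lumen_center_mm[1]
  # a wall point inside the arc (140 deg) now reads as lumen
  th <- 140 * pi / 180
  a <- spec$lumen_semi_axes_mm[1]; b <- spec$lumen_semi_axes_mm[2]
  r_in <- 1 / sqrt((sin(th) / b)^2 + (cos(th) / a)^2)
  zz <- z0 + cos(th) * (r_in + spec$wall_thickness_mm / 2)
  xx <- sin(th) * (r_in + spec$wall_thickness_mm / 2)
  val <- px[round(zz / sp) + 1, round(xx / sp) + spec$apex_column_px]
  expect_lt(val, spec$tissue_intensity)

  cl <- generate_phantom(small_spec(clutter_blob_count = 4), seed = 9)
  cl2 <- generate_phantom(small_spec(clutter_blob_count = 4), seed = 9)
  expect_identical(cl$image$pixels, cl2$image$pixels)
})

test_that("dataset manifests are reproducible and span the ranges", {
  d1 <- generate_dataset(10, seed = 7, render = FALSE)
  d2 <- generate_dataset(10, seed = 7, render = FALSE)
  expect_equal(nrow(d1$manifest), 10)
  expect_identical(d1$manifest, d2$manifest)
  expect_error(generate_dataset(0), "n must be")
  expect_error(generate_dataset(5, thickness_range_mm = c(5, 1.5)), "ranges")

  d50 <- generate_dataset(50, thickness_range_mm = c(1.5, 5), seed = 3,
                          render = FALSE)
  expect_lt(min(d50$manifest$thickness_mm), 1.9)
  expect_gt(max(d50$manifest$thickness_mm), 4.6)
  # subject blocks support subject-level folds
  expect_equal(length(unique(d50$manifest$subject_id)), 10)
  expect_true(all(table(d50$manifest$subject_id) == 5))
})

test_that("rendered datasets are consistent with their manifests", {
  ds <- generate_dataset(3, seed = 5, base_spec = small_spec())
  expect_length(ds$samples, 3)
  for (i in 1:3)
    expect_equal(ds$samples[[i]]$true_thickness_mm,
                 ds$manifest$thickness_mm[i])
})
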