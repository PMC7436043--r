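# Dual parallel-line wall tracker.

ideal_costs <- function(H = 36, W = 30, outer = 10, inner = 23) {
  g <- matrix(0, H, W)
  g[outer, ] <- 10     # rising tissue -> wall edge
  g[inner, ] <- -10    # falling wall -> lumen edge
  list(g = g - min(g), g_inv = max(g) - g)
}

test_that("the search box crops around the mid-top of the contour", {
  img <- bmode_image(matrix(50, 880, 1068), 0.2)
  # circular inner boundary, radius 20 mm, centre depth 60 mm: anterior
  # boundary at depth 40 mm
  th <- (0:359) * pi / 180
  cont <- tibble::tibble(angle_deg = 0:359,
                         x_px = 534 + 100 * sin(th),
                         y_px = 301 + 100 * cos(th))
  reg <- crop_search_region(img, cont, mdp_params())
  expect_equal(dim(reg$crop), c(70, 30))   # (8+6)/0.2 by 6/0.2
  depths_mm <- (reg$row_offset_px + c(1, nrow(reg$crop)) - 1) * 0.2
  expect_equal(depths_mm[1], 32, tolerance = 0.4)
  expect_equal(depths_mm[2], 45.8, tolerance = 0.4)

  far <- dplyr::mutate(cont, x_px = x_px + 5000)
  expect_error(crop_search_region(img, far), "outside the image")
})

test_that("node costs put the two boundaries on opposite edge polarities", {
  reg <- structure(list(crop = matrix(7, 40, 10), row_offset_px = 0L,
                        col_offset_px = 0L, pixel_spacing_mm = 0.2),
                   class = "wall_search_region")
  nc <- wall_node_costs(reg)
  expect_lt(max(abs(nc$g)), 1e-10)
  expect_lt(diff(range(nc$g_inv)), 1e-10)

  # single dark -> bright edge: the two fields prefer different rows
  crop <- matrix(20, 40, 10); crop[20:40, ] <- 200
  nc <- wall_node_costs(structure(list(crop = crop, pixel_spacing_mm = 0.2),
                                  class = "wall_search_region"))
  expect_false(which.min(nc$g[, 5]) == which.min(nc$g_inv[, 5]))

  # noise-free phantom crop: g_inv argmin at the outer (rising) edge and
  # g argmin at the inner (falling) edge, column by column
  ph <- generate_phantom(phantom_spec(speckle_scale = 0, blur_sigma_px = 0,
                                      wall_thickness_mm = 3))
  reg <- crop_search_region(ph$image, ph$inner_contour, mdp_params())
  nc <- wall_node_costs(reg)
  inner_rows <- apply(nc$g, 2, which.min)
  outer_rows <- apply(nc$g_inv, 2, which.min)
  expect_true(all(outer_rows < inner_rows))
  sep_mm <- (inner_rows - outer_rows) * 0.2
  expect_true(all(abs(sep_mm - 3) <= 0.4))
})

test_that("ideal parallel edges are tracked exactly", {
  nc <- ideal_costs()
  wb <- mdp_dual_path(nc$g, nc$g_inv, mdp_params(), spacing_mm = 0.2)
  expect_equal(wb$outer_row_per_col, rep(10L, 30))
  expect_equal(wb$inner_row_per_col, rep(23L, 30))
  res <- measure_thickness(wb)
  expect_equal(res$mean_thickness_mm, 2.6)
})

test_that("a uniform crop falls back to the deterministic tie-break", {
  g <- matrix(1, 40, 8)
  wb <- mdp_dual_path(g, g, mdp_params(), spacing_mm = 0.2)
  expect_equal(wb$outer_row_per_col, rep(1L, 8))
  expect_equal(wb$inner_row_per_col, rep(1L + 6L, 8))   # smallest feasible d
})

test_that("the dual-line optimum matches exhaustive enumeration", {
  set.seed(202)
  for (i in 1:30) {
    H <- sample(8:12, 1); W <- sample(3:6, 1)
    go <- matrix(sample(0:9, H * W, replace = TRUE), H, W)
    gi <- matrix(sample(0:9, H * W, replace = TRUE), H, W)
    prm <- mdp_params(dmin_mm = 2 * 0.2, dmax_mm = 6.4 * 0.2)
    wb <- mdp_dual_path(gi, go, prm, spacing_mm = 0.2)
    # d bounds: strict (2, 6.4) px -> separations 3..6
    expect_equal(wb$total_cost,
                 brute_mdp(go, gi, dmin_px = 3, dmax_px = 6))
    sep <- wb$inner_row_per_col - wb$outer_row_per_col
    expect_true(all(sep >= 3 & sep <= 6))
    expect_true(all(abs(diff(wb$outer_row_per_col)) <= 1))
    expect_true(all(abs(diff(wb$inner_row_per_col)) <= 1))
  }
})

test_that("each penalty factor is an exact twenty percent surcharge", {
  # one line steps by 1 px; the other and the separation change are
  # isolated via the alpha switches
  big <- 1e6
  H <- 20
  go <- matrix(big, H, 2); gi <- matrix(big, H, 2)
  go[5, 1] <- 0; gi[10, 1] <- 0          # start state (5, 10)
  go[6, 2] <- 3; gi[10, 2] <- 0          # outer moves +1, inner stays
  prm <- mdp_params(alpha1 = 0.2, alpha2 = 0.2, alpha3 = 0,
                    dmin_mm = 1, dmax_mm = 7)
  wb <- mdp_dual_path(gi, go, prm, spacing_mm = 1)
  expect_equal(wb$outer_row_per_col, c(5L, 6L))
  expect_equal(wb$inner_row_per_col, c(10L, 10L))
  expect_equal(wb$total_cost, 3 * 1.2)

  # separation-change penalty isolated the same way
  prm3 <- mdp_params(alpha1 = 0, alpha2 = 0, alpha3 = 0.2,
                     dmin_mm = 1, dmax_mm = 7)
  wb3 <- mdp_dual_path(gi, go, prm3, spacing_mm = 1)
  expect_equal(wb3$total_cost, 3 * 1.2)
})

test_that("the parallelism penalty controls separation variability", {
  # field that pays the inner line to wander
  H <- 30; W <- 12
  go <- matrix(5, H, W); gi <- matrix(5, H, W)
  go[10, ] <- 1
  wander <- 17 + rep(c(0, 1), length.out = W)
  gi[cbind(wander, seq_len(W))] <- 1
  loose <- mdp_dual_path(gi, go, mdp_params(alpha3 = 0), spacing_mm = 0.2)
  expect_gt(length(unique(loose$inner_row_per_col - loose$outer_row_per_col)),
            1)
  stiff <- mdp_dual_path(gi, go, mdp_params(alpha3 = 100), spacing_mm = 0.2)
  expect_equal(length(unique(stiff$inner_row_per_col -
                               stiff$outer_row_per_col)), 1L)
})

test_that("thickness conversion and bounds behave", {
  nc <- ideal_costs(inner = 23)
  wb <- mdp_dual_path(nc$g, nc$g_inv, mdp_params(), spacing_mm = 0.2)
  expect_equal(measure_thickness(wb)$mean_thickness_mm, 2.6)

  wb2 <- wb
  wb2$inner_row_per_col <- wb$outer_row_per_col + c(10L, 12L, 14L,
                                                    rep(12L, 27))
  res2 <- measure_thickness(wb2)
  expect_equal(mean(res2$per_column_thickness_mm[1:3]), 2.4)

  wb3 <- wb
  wb3$inner_row_per_col <- wb$outer_row_per_col   # degenerate separation
  expect_error(measure_thickness(wb3), "below")
})

test_that("wall measurement recovers known phantom thickness", {
  for (t in c(3, 6.5)) {
    ph <- generate_phantom(phantom_spec(speckle_scale = 0, blur_sigma_px = 0,
                                        wall_thickness_mm = t))
    res <- measure_wall_from_image(ph$image, ph$inner_contour)
    expect_lt(abs(res$mean_thickness_mm - t), if (t > 6) 0.5 else 0.2)
    expect_gte(res$mean_thickness_mm, 1)
    expect_lte(res$mean_thickness_mm, 7)
  }
})
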