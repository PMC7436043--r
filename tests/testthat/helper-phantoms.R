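# Small phantom profile used by unit tests where full resolution is not the
# point: 220 x 268 px at 0.8 mm/px keeps the pipeline geometry intact at a
# fraction of the cost.
small_spec <- function(...) {
  phantom_spec(image_height_px = 220, image_width_px = 268,
               pixel_spacing_mm = 0.8, ...)
}

# Tiny phantoms for the network tests: 64 x 80 px at 2 mm/px.
unet_phantoms <- function(n, seed = 11, thickness = c(4, 6)) {
  base <- phantom_spec(image_height_px = 64, image_width_px = 80,
                       pixel_spacing_mm = 2.0, wall_thickness_mm = 5,
                       blur_sigma_px = 1)
  generate_dataset(n, thickness_range_mm = thickness,
                   semi_axes_range_mm = c(20, 35), images_per_subject = 4,
                   seed = seed, base_spec = base)
}
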