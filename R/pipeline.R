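# File I/O and end-to-end pipeline glue.

#' Read an 8-bit grayscale B-mode image
#'
#' Reads PNG (or TIFF when the tiff package is installed), collapses colour
#' channels to gray, and attaches physical spacing and probe geometry.
#'
#' @param path PNG/TIFF file.
#' @param pixel_spacing_mm Pixel spacing in mm (default 0.2).
#' @param probe A [probe_geometry()].
#' @return A [bmode_image()].
#' @export
read_bmode <- function(path, pixel_spacing_mm = 0.2,
                       probe = probe_geometry()) {
  if (!file.exists(path)) stop_detrusor(sprintf("cannot read image: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_detrusor("the tiff package is required to read TIFF images")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(px)) == 3) px <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE],
                                        c(1, 2), mean)
  bmode_image(round(px * 255), pixel_spacing_mm, probe)
}

#' Write a binary mask as a 0/255 PNG
#' @param mask Logical/0-1 matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask != 0) * 1.0, path)
  invisible(path)
}

#' Read a 0/255 mask PNG as a logical matrix
#' @param path PNG file.
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px > 0.5
}

#' Write / read a contour as CSV (angle_deg, x_px, y_px)
#' @param contour A `contour` tibble.
#' @param path CSV path.
#' @export
write_contour_csv <- function(contour, path) {
  write.csv(as.data.frame(contour)[, c("angle_deg", "x_px", "y_px")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  structure(df, class = c("contour", class(df)), closed = TRUE,
            center = list(row = mean(df$y_px), col = mean(df$x_px)))
}

#' Extract the outer boundary contour of a binary mask
#'
#' Samples 360 rays from the mask centroid and records the outermost
#' foreground radius per angle; intended for star-shaped masks such as a
#' segmented bladder lumen.
#'
#' @param mask Logical matrix.
#' @return A `contour` tibble.
#' @export
mask_to_contour <- function(mask) {
  if (!any(mask)) stop_detrusor("mask is empty")
  ctr <- list(row = mean(row(mask)[mask]), col = mean(col(mask)[mask]))
  theta <- (0:359) * pi / 180
  rmax <- max(dim(mask))
  rr <- seq(0.5, rmax, by = 0.5)
  rows <- ctr$row + outer(cos(theta), rr)
  cols <- ctr$col + outer(sin(theta), rr)
  ok <- rows >= 1 & rows <= nrow(mask) & cols >= 1 & cols <= ncol(mask)
  inside <- matrix(FALSE, 360, length(rr))
  inside[ok] <- mask[cbind(round(rows[ok]), round(cols[ok]))]
  ridx <- apply(inside, 1, function(v) if (any(v)) max(which(v)) else 0L)
  r_px <- rr[pmax(ridx, 1)] * (ridx > 0)
  out <- tibble::tibble(angle_deg = 0:359,
                        x_px = ctr$col + r_px * sin(theta),
                        y_px = ctr$row + r_px * cos(theta))
  structure(out, class = c("contour", class(out)), closed = TRUE,
            center = ctr)
}

#' Pipeline configuration
#'
#' Bundles pixel spacing, probe geometry and the DP / MDP parameters, plus a
#' seed and verbosity flag. Round-trips through YAML; unknown keys are
#' rejected.
#'
#' @param pixel_spacing_mm Pixel spacing (default 0.2 mm).
#' @param probe_width_mm,fov_deg,apex_column_px Probe geometry.
#' @param dp A [dp_params()].
#' @param mdp An [mdp_params()].
#' @param seed Pipeline seed.
#' @param verbose Log stage timings (default FALSE).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_spacing_mm = 0.2, probe_width_mm = 30,
                            fov_deg = 60, apex_column_px = NULL,
                            dp = dp_params(), mdp = mdp_params(),
                            seed = 1L, verbose = FALSE) {
  structure(list(pixel_spacing_mm = pixel_spacing_mm,
                 probe_width_mm = probe_width_mm, fov_deg = fov_deg,
                 apex_column_px = apex_column_px,
                 dp = dp, mdp = mdp, seed = as.integer(seed),
                 verbose = isTRUE(verbose)), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_config_yaml <- function(x, path) {
  stopifnot(inherits(x, "pipeline_config"))
  lst <- unclass(x)
  lst$dp <- unclass(lst$dp)
  lst$mdp <- unclass(lst$mdp)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- c("pixel_spacing_mm", "probe_width_mm", "fov_deg",
             "apex_column_px", "dp", "mdp", "seed", "verbose")
  extra <- setdiff(names(lst), known)
  if (length(extra))
    stop_detrusor(paste("unknown config keys:", paste(extra, collapse = ", ")))
  dp <- if (!is.null(lst$dp)) do.call(dp_params, lst$dp) else dp_params()
  mdp <- if (!is.null(lst$mdp)) do.call(mdp_params, lst$mdp) else mdp_params()
  pipeline_config(
    pixel_spacing_mm = lst$pixel_spacing_mm %||% 0.2,
    probe_width_mm = lst$probe_width_mm %||% 30,
    fov_deg = lst$fov_deg %||% 60,
    apex_column_px = lst$apex_column_px,
    dp = dp, mdp = mdp, seed = lst$seed %||% 1L,
    verbose = lst$verbose %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full segmentation + wall-thickness pipeline on one image
#'
#' Reads the image, segments the bladder sac (DP by default, or a trained
#' U-Net model when supplied), measures the anterior wall thickness with the
#' dual-line tracker, and optionally writes the lumen mask (PNG), the inner
#' contour (CSV) and the thickness result (JSON).
#'
#' @param image_path Input PNG/TIFF.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param unet_model Optional trained [unet_init()] model; when given, the
#'   sac is segmented by the network instead of the DP (the image must match
#'   the model input shape).
#' @return A list with `segmentation`, `thickness`, `outputs` (paths or
#'   NULL) and stage `timings_s`.
#' @export
run_pipeline <- function(image_path, config = pipeline_config(),
                         out_dir = NULL, unet_model = NULL) {
  t0 <- proc.time()[["elapsed"]]
  probe <- probe_geometry(config$probe_width_mm, config$fov_deg,
                          config$apex_column_px)
  img <- read_bmode(image_path, config$pixel_spacing_mm, probe)
  t_read <- proc.time()[["elapsed"]]
  if (is.null(unet_model)) {
    seg <- segment_bladder_dp(img, config$dp)
    contour <- seg$contour
    mask <- seg$mask
  } else {
    mask <- unet_predict(unet_model, img$pixels)
    contour <- mask_to_contour(mask)
    seg <- list(mask = mask, contour = contour, method = "unet")
  }
  t_seg <- proc.time()[["elapsed"]]
  thick <- measure_wall_from_image(img, contour, config$mdp)
  t_wall <- proc.time()[["elapsed"]]
  outputs <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(out_dir, tools::file_path_sans_ext(basename(image_path)))
    outputs <- list(mask = paste0(stem, "_mask.png"),
                    contour = paste0(stem, "_contour.csv"),
                    thickness = paste0(stem, "_thickness.json"))
    write_mask_png(mask, outputs$mask)
    write_contour_csv(contour, outputs$contour)
    jsonlite::write_json(list(
      mean_thickness_mm = thick$mean_thickness_mm,
      per_column_thickness_mm = thick$per_column_thickness_mm,
      boundaries = thick$boundaries_image,
      parameters = unclass(config$mdp)),
      outputs$thickness, auto_unbox = TRUE, digits = NA)
  }
  timings <- c(read = t_read - t0, segment = t_seg - t_read,
               wall = t_wall - t_seg)
  if (config$verbose)
    message(sprintf("[detrusor] %s: read %.2fs, segment %.2fs, wall %.2fs; mean thickness %.2f mm",
                    basename(image_path), timings[1], timings[2], timings[3],
                    thick$mean_thickness_mm))
  list(segmentation = seg, thickness = thick, outputs = outputs,
       timings_s = timings)
}

#' Run the pipeline over a manifest of images
#'
#' Processes every row of a manifest (data frame or CSV path with column
#' `image_path`, optional `mask_path` and `thickness_mm` ground truth).
#' Missing files are reported as warnings and skipped. When ground truth is
#' present, a summary with mean Dice and thickness RMSE is appended.
#'
#' @param manifest Data frame or CSV path.
#' @param config A [pipeline_config()].
#' @return A list with `results` (per-image tibble) and `summary` (tibble or
#'   NULL).
#' @export
batch_run <- function(manifest, config = pipeline_config()) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  manifest <- tibble::as_tibble(manifest)
  if (!nrow(manifest)) stop_detrusor("empty manifest")
  if (!"image_path" %in% names(manifest))
    stop_detrusor("manifest needs an image_path column")
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$image_path[i]
    if (!file.exists(p)) {
      warning(sprintf("missing image, skipped: %s", p))
      next
    }
    res <- run_pipeline(p, config)
    row <- tibble::tibble(image_path = p,
                          mean_thickness_mm = res$thickness$mean_thickness_mm,
                          lumen_area_px = sum(res$segmentation$mask))
    if ("mask_path" %in% names(manifest) && !is.na(manifest$mask_path[i]) &&
        file.exists(manifest$mask_path[i]))
      row$dice <- dice(res$segmentation$mask, read_mask_png(manifest$mask_path[i]))
    if ("thickness_mm" %in% names(manifest))
      row$true_thickness_mm <- manifest$thickness_mm[i]
    rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) stop_detrusor("no readable images in manifest")
  results <- dplyr::bind_rows(rows)
  summary <- NULL
  if ("dice" %in% names(results) || "true_thickness_mm" %in% names(results)) {
    summary <- tibble::tibble(n = nrow(results))
    if ("dice" %in% names(results)) summary$mean_dice <- mean(results$dice)
    if ("true_thickness_mm" %in% names(results))
      summary$thickness_rmse_mm <- rmse(results$mean_thickness_mm,
                                        results$true_thickness_mm)
  }
  list(results = results, summary = summary)
}
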