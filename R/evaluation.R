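#' Dice similarity index between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param maskA,maskB Logical (or 0/1) matrices of the same shape.
#' @return Dice index in \[0, 1\].
#' @export
dice <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB)))
    stop_detrusor("masks must have the same shape")
  a <- as.logical(maskA); b <- as.logical(maskB)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

contour_points <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(cbind(x$x_px, x$y_px))
  stop_detrusor("contour must be a 2-column matrix or a data frame with x_px, y_px")
}

#' Symmetric Hausdorff distance between two contours, in mm
#'
#' The larger of the two directed distances `max_a min_b |a - b|`, scaled by
#' the pixel spacing.
#'
#' @param contourA,contourB Contours (data frames with `x_px`, `y_px`, or
#'   2-column point matrices).
#' @param spacing_mm Pixel spacing in mm.
#' @return Hausdorff distance in mm.
#' @export
hausdorff_mm <- function(contourA, contourB, spacing_mm = 0.2) {
  A <- contour_points(contourA); B <- contour_points(contourB)
  if (!nrow(A) || !nrow(B)) stop_detrusor("contours must be non-empty")
  d2 <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
  # directed maxima of the min point distances, then symmetrise
  h <- sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
  h * spacing_mm
}

#' Root-mean-square error between paired measurements
#'
#' @param x,y Numeric vectors of equal length (>= 1).
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y) || !length(x))
    stop_detrusor("x and y must have equal, nonzero length")
  sqrt(mean((x - y)^2))
}

#' Bland-Altman agreement analysis
#'
#' Computes the differences `A - B`, their mean (bias), sample standard
#' deviation and the 95 percent limits of agreement `bias +/- 1.96 sd`,
#' together with the per-pair data for the standard mean-vs-difference plot.
#'
#' @param measA,measB Paired numeric vectors, length >= 2.
#' @return An object of class `bland_altman` with fields `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n` and a `data` tibble (`mean`, `difference`).
#' @export
bland_altman <- function(measA, measB) {
  if (length(measA) != length(measB) || length(measA) < 2)
    stop_detrusor("need paired measurements with n >= 2")
  d <- measA - measB
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d),
                 data = tibble::tibble(mean = (measA + measB) / 2,
                                       difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.3f, LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Pairwise observer agreement table
#'
#' RMSE between every pair of measurement series and between each series
#' and a reference (by default the per-case mean across observers),
#' formatted as a long tibble.
#'
#' @param observers Named list of numeric vectors, one per observer/method,
#'   all of equal length (aligned per case).
#' @param reference Optional reference vector; `NULL` uses the per-case mean
#'   over `observers`.
#' @return A tibble with columns `a`, `b`, `rmse`.
#' @export
observer_table <- function(observers, reference = NULL) {
  stopifnot(is.list(observers), length(observers) >= 1)
  lens <- lengths(observers)
  if (length(unique(lens)) != 1)
    stop_detrusor("all observer series must be aligned (equal length)")
  if (is.null(names(observers)) || any(names(observers) == ""))
    names(observers) <- paste0("obs", seq_along(observers))
  if (is.null(reference))
    reference <- rowMeans(do.call(cbind, observers))
  else if (length(reference) != lens[1])
    stop_detrusor("reference must align with the observer series")
  nm <- names(observers)
  rows <- list()
  for (i in seq_along(observers))
    rows[[length(rows) + 1]] <- tibble::tibble(
      a = nm[i], b = "reference", rmse = rmse(observers[[i]], reference))
  if (length(observers) > 1)
    for (i in seq_len(length(observers) - 1))
      for (j in (i + 1):length(observers))
        rows[[length(rows) + 1]] <- tibble::tibble(
          a = nm[i], b = nm[j], rmse = rmse(observers[[i]], observers[[j]]))
  dplyr::bind_rows(rows)
}
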