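# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so package randomness never leaks into sessions.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Separable Gaussian blur with replicate (edge-clamped) boundary handling;
# sigma = 0 is the identity. Exact on constant fields, no wrap-around
# between the top and bottom of the image.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (j in -r:r)
    out <- out + k[j + r + 1] * m[pmin(pmax(seq_len(nr) + j, 1), nr), ,
                                  drop = FALSE]
  m2 <- matrix(0, nr, nc)
  for (j in -r:r)
    m2 <- m2 + k[j + r + 1] * out[, pmin(pmax(seq_len(nc) + j, 1), nc),
                                  drop = FALSE]
  m2
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
# Out-of-bounds positions return NA.
bilinear_at <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  r0 <- pmin(pmax(floor(rows), 1), nr - 1)
  c0 <- pmin(pmax(floor(cols), 1), nc - 1)
  fr <- rows - r0
  fc <- cols - c0
  v00 <- m[cbind(r0, c0)]
  v10 <- m[cbind(r0 + 1L, c0)]
  v01 <- m[cbind(r0, c0 + 1L)]
  v11 <- m[cbind(r0 + 1L, c0 + 1L)]
  out <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out[!ok] <- NA_real_
  out
}

stop_center <- function(msg) {
  stop(errorCondition(msg, class = c("center_detection_error", "detrusor_error",
                                     "error", "condition")))
}

stop_detrusor <- function(msg) {
  stop(errorCondition(msg, class = c("detrusor_error", "error", "condition")))
}
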