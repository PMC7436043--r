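# U-Net-style encoder-decoder segmenter.
#
# Implemented directly on BLAS matrix products: 3x3 convolutions via im2col,
# max-pooling / nearest upsampling by array reshaping, explicit backward
# passes, Adam updates. Activations are H x W x C arrays.

#' Per-class balancing weights for the segmentation loss
#'
#' `weight_j = max(counts) / count_j`, so the rarest class gets the largest
#' weight and a balanced problem gets unit weights.
#'
#' @param label_counts Positive pixel counts per class.
#' @return Numeric weights, same length/names as `label_counts`.
#' @export
class_weights <- function(label_counts) {
  if (any(label_counts <= 0))
    stop_detrusor("every class must have a positive pixel count")
  max(label_counts) / label_counts
}

#' Weighted categorical cross-entropy
#'
#' Mean over samples of `-sum_j y_ij log(yhat_ij) w_j`; with unit weights
#' this is the standard categorical cross-entropy. Predictions are clipped
#' away from zero by `eps`.
#'
#' @param y One-hot true labels: `n x m` matrix (or an array whose last
#'   dimension is the class axis).
#' @param yhat Predicted class probabilities, same shape as `y`.
#' @param weights Per-class weights, length `m`.
#' @param eps Clipping floor for the predicted probabilities.
#' @return Scalar loss.
#' @export
weighted_cce <- function(y, yhat, weights = NULL, eps = 1e-7) {
  if (!all(dim(y) == dim(yhat)))
    stop_detrusor("y and yhat shapes differ")
  dy <- dim(y)
  m <- dy[length(dy)]
  ym <- matrix(y, ncol = m)
  pm <- matrix(yhat, ncol = m)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop_detrusor("need one weight per class")
  mean(-rowSums(ym * log(pmax(pm, eps)) *
                  matrix(weights, nrow(ym), m, byrow = TRUE)))
}

#' Random elastic deformation of an image/mask pair
#'
#' Draws independent Gaussian displacements at a coarse control grid,
#' bilinearly upsamples them to a smooth dense displacement field, and
#' applies the same field to the image (bilinear interpolation) and the
#' mask (nearest neighbour). Deterministic per seed; zero magnitude is the
#' identity.
#'
#' @param image Numeric matrix.
#' @param mask Logical/numeric matrix, same shape.
#' @param grid_points Control points per axis (default 5).
#' @param magnitude_px Displacement standard deviation in pixels (default 3,
#'   chosen so a convex phantom mask keeps Dice >= 0.8 with its deformation).
#' @param seed RNG seed.
#' @return List with deformed `image` and `mask`.
#' @export
elastic_augment <- function(image, mask, grid_points = 5, magnitude_px = 3,
                            seed = 1) {
  if (!all(dim(image) == dim(mask)))
    stop_detrusor("image and mask shapes differ")
  h <- nrow(image); w <- ncol(image)
  if (magnitude_px == 0) return(list(image = image, mask = mask))
  ctrl <- with_seed(seed, list(
    dr = matrix(rnorm(grid_points^2, 0, magnitude_px), grid_points),
    dc = matrix(rnorm(grid_points^2, 0, magnitude_px), grid_points)))
  qr <- matrix((seq_len(h) - 1) / (h - 1) * (grid_points - 1) + 1, h, w)
  qc <- matrix((seq_len(w) - 1) / (w - 1) * (grid_points - 1) + 1, h, w,
               byrow = TRUE)
  fr <- matrix(bilinear_at(ctrl$dr, as.vector(qr), as.vector(qc)), h, w)
  fc <- matrix(bilinear_at(ctrl$dc, as.vector(qr), as.vector(qc)), h, w)
  src_r <- pmin(pmax(row(image) + fr, 1), h)
  src_c <- pmin(pmax(col(image) + fc, 1), w)
  img2 <- matrix(bilinear_at(image, as.vector(src_r), as.vector(src_c)), h, w)
  mask2 <- matrix(mask[cbind(as.vector(round(src_r)), as.vector(round(src_c)))],
                  h, w)
  list(image = img2, mask = mask2)
}

#' Subject-level cross-validation folds
#'
#' Partitions subjects (not images) into `k` folds of near-equal subject
#' count, so all images of a subject share a fold.
#'
#' @param subject_ids Per-image subject identifiers.
#' @param k Number of folds.
#' @param seed RNG seed for the subject shuffle.
#' @return Integer fold assignment per image, with a `subjects` attribute
#'   (tibble: subject_id, fold).
#' @export
subject_folds <- function(subject_ids, k, seed = 1) {
  u <- unique(subject_ids)
  if (length(u) < k)
    stop_detrusor("fewer distinct subjects than folds")
  shuffled <- with_seed(seed, sample(u))
  sizes <- rep(length(u) %/% k, k) + (seq_len(k) <= length(u) %% k)
  fold_of <- rep.int(seq_len(k), sizes)
  map <- setNames(fold_of, shuffled)
  out <- unname(map[as.character(subject_ids)])
  attr(out, "subjects") <- tibble::tibble(subject_id = shuffled,
                                          fold = fold_of)
  out
}

#' Architecture of the compact U-Net segmenter
#'
#' A standard U-Net ladder: `levels` resolution levels with two 3x3
#' convolutions + ReLU each, max-pooling between encoder levels (10 encoder
#' convolutions and 4 pools at the default 5 levels), nearest-neighbour
#' upsampling followed by a 3x3 up-convolution and skip concatenation in the
#' decoder (9 decoder convolutions including the final 1x1), softmax output
#' over `classes`. Feature widths double per level from `base_filters`.
#' Dropout is applied in the deepest encoder levels during training.
#'
#' @param input_shape `c(H, W)`; both must be divisible by
#'   `2^(levels - 1)`.
#' @param base_filters Feature maps at the top level (default 8 for the
#'   desk-scale profile).
#' @param levels Resolution levels (default 5, i.e. 4 poolings).
#' @param classes Output classes (default 2).
#' @param dropout_rate Encoder dropout rate (default 0.5).
#' @param dropout_levels Encoder levels that apply dropout (default the two
#'   deepest).
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(input_shape = c(64, 80), base_filters = 8, levels = 5,
                      classes = 2, dropout_rate = 0.5,
                      dropout_levels = c(levels - 1, levels)) {
  div <- 2^(levels - 1)
  if (any(input_shape %% div != 0))
    stop_detrusor(sprintf("input dimensions must be divisible by %d (pad the input)", div))
  structure(list(input_shape = input_shape, base_filters = base_filters,
                 levels = levels, classes = classes,
                 dropout_rate = dropout_rate,
                 dropout_levels = dropout_levels,
                 filters = base_filters * 2^(seq_len(levels) - 1)),
            class = "unet_spec")
}

glorot_uniform <- function(n_in, n_out, k2 = 9) {
  lim <- sqrt(6 / (k2 * n_in + k2 * n_out))
  matrix(runif(k2 * n_in * n_out, -lim, lim), k2 * n_in, n_out)
}

#' Initialise U-Net weights (Glorot uniform)
#'
#' @param spec A [unet_spec()].
#' @param seed RNG seed.
#' @return An object of class `unet_model` (spec + named parameter list).
#' @export
unet_init <- function(spec, seed = 1) {
  L <- spec$levels
  f <- spec$filters
  params <- with_seed(seed, {
    p <- list()
    cin <- 1
    for (l in seq_len(L)) {
      p[[sprintf("enc%d_W1", l)]] <- glorot_uniform(cin, f[l])
      p[[sprintf("enc%d_b1", l)]] <- numeric(f[l])
      p[[sprintf("enc%d_W2", l)]] <- glorot_uniform(f[l], f[l])
      p[[sprintf("enc%d_b2", l)]] <- numeric(f[l])
      cin <- f[l]
    }
    for (l in rev(seq_len(L - 1))) {
      p[[sprintf("dec%d_Wu", l)]] <- glorot_uniform(cin, f[l])
      p[[sprintf("dec%d_bu", l)]] <- numeric(f[l])
      p[[sprintf("dec%d_W1", l)]] <- glorot_uniform(2 * f[l], f[l])
      p[[sprintf("dec%d_b1", l)]] <- numeric(f[l])
      p[[sprintf("dec%d_W2", l)]] <- glorot_uniform(f[l], f[l])
      p[[sprintf("dec%d_b2", l)]] <- numeric(f[l])
      cin <- f[l]
    }
    p[["final_W"]] <- glorot_uniform(f[1], spec$classes, k2 = 1)
    p[["final_b"]] <- numeric(spec$classes)
    p
  })
  structure(list(spec = spec, params = params), class = "unet_model")
}

# ---- layer primitives -------------------------------------------------------

# 3x3 same-padding convolution; returns output and the im2col matrix.
conv3_fwd <- function(x, W, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  pad <- array(0, c(h + 2, w + 2, cin))
  pad[2:(h + 1), 2:(w + 1), ] <- x
  M <- matrix(0, h * w, 9 * cin)
  k <- 1L
  for (dj in 0:2) for (di in 0:2) {
    M[, ((k - 1) * cin + 1):(k * cin)] <-
      matrix(pad[(1 + di):(h + di), (1 + dj):(w + dj), ], h * w, cin)
    k <- k + 1L
  }
  out <- M %*% W
  out <- sweep(out, 2, b, `+`)
  list(out = array(out, c(h, w, ncol(W))), M = M)
}

# Backward of conv3_fwd: returns gradients wrt input, W, b. dX is computed
# as a convolution of dOut with the spatially flipped, in/out-swapped W.
conv3_bwd <- function(dout, M, W, cin) {
  d <- dim(dout); h <- d[1]; w <- d[2]; cout <- d[3]
  dmat <- matrix(dout, h * w, cout)
  dW <- crossprod(M, dmat)
  db <- colSums(dmat)
  warr <- array(W, c(cin, 9, cout))
  wb <- aperm(warr[, 9:1, , drop = FALSE], c(3, 2, 1))   # cout x 9 x cin
  Wb <- matrix(wb, 9 * cout, cin)
  dX <- conv3_fwd(dout, Wb, numeric(cin))$out
  list(dX = dX, dW = dW, db = db)
}

conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  out <- matrix(x, d[1] * d[2], d[3]) %*% W
  out <- sweep(out, 2, b, `+`)
  array(out, c(d[1], d[2], ncol(W)))
}

conv1_bwd <- function(dout, x, W) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  dmat <- matrix(dout, d[1] * d[2], ncol(W))
  list(dX = array(dmat %*% t(W), d), dW = crossprod(xm, dmat),
       db = colSums(dmat))
}

relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, mask = m)
}

maxpool_fwd <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]; cc <- d[3]
  x4 <- array(x, c(2, h / 2, w, cc))
  s1 <- x4[1, , , , drop = FALSE] >= x4[2, , , , drop = FALSE]
  a <- x4[1, , , , drop = FALSE] * s1 + x4[2, , , , drop = FALSE] * !s1
  a <- array(a, c(h / 2, 2, w / 2, cc))
  s2 <- a[, 1, , , drop = FALSE] >= a[, 2, , , drop = FALSE]
  out <- a[, 1, , , drop = FALSE] * s2 + a[, 2, , , drop = FALSE] * !s2
  list(out = array(out, c(h / 2, w / 2, cc)),
       s1 = array(s1, c(h / 2, w, cc)), s2 = array(s2, c(h / 2, w / 2, cc)))
}

maxpool_bwd <- function(dout, pool, full_dim) {
  h <- full_dim[1]; w <- full_dim[2]; cc <- full_dim[3]
  da <- array(0, c(h / 2, 2, w / 2, cc))
  da[, 1, , ] <- dout * pool$s2
  da[, 2, , ] <- dout * !pool$s2
  da <- array(da, c(h / 2, w, cc))
  dx4 <- array(0, c(2, h / 2, w, cc))
  dx4[1, , , ] <- da * pool$s1
  dx4[2, , , ] <- da * !pool$s1
  array(dx4, full_dim)
}

upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample_bwd <- function(dout) {
  d <- dim(dout); h <- d[1]; w <- d[2]; cc <- d[3]
  a <- array(dout, c(2, h / 2, w, cc))
  a <- array(a[1, , , ] + a[2, , , ], c(h / 2, 2, w / 2, cc))
  a[, 1, , ] + a[, 2, , ]
}

softmax3 <- function(z) {
  d <- dim(z)
  zm <- matrix(z, d[1] * d[2], d[3])
  zm <- zm - apply(zm, 1, max)
  e <- exp(zm)
  array(e / rowSums(e), d)
}

# ---- forward / backward -----------------------------------------------------

unet_forward <- function(model, image, training = FALSE, dropout_seed = NULL) {
  spec <- model$spec
  p <- model$params
  L <- spec$levels
  x <- array(image / 255, c(dim(image), 1))
  cache <- list(enc = vector("list", L), dec = vector("list", L),
                skips = vector("list", L))
  drop_masks <- vector("list", L)
  if (training && spec$dropout_rate > 0 && !is.null(dropout_seed))
    drop_masks <- with_seed(dropout_seed, {
      lapply(seq_len(L), function(l) {
        if (!(l %in% spec$dropout_levels)) return(NULL)
        dm <- dim_at_level(spec, l)
        array(runif(prod(dm)) >= spec$dropout_rate, dm) / (1 - spec$dropout_rate)
      })
    })
  h <- x
  for (l in seq_len(L)) {
    cc <- list()
    cc$c1 <- conv3_fwd(h, p[[sprintf("enc%d_W1", l)]], p[[sprintf("enc%d_b1", l)]])
    cc$r1 <- relu_fwd(cc$c1$out)
    cc$c2 <- conv3_fwd(cc$r1$out, p[[sprintf("enc%d_W2", l)]], p[[sprintf("enc%d_b2", l)]])
    cc$r2 <- relu_fwd(cc$c2$out)
    h <- cc$r2$out
    if (!is.null(drop_masks[[l]])) {
      cc$drop <- drop_masks[[l]]
      h <- h * cc$drop
    }
    if (l < L) {
      cache$skips[[l]] <- h
      cc$pre_pool_dim <- dim(h)
      cc$pool <- maxpool_fwd(h)
      h <- cc$pool$out
    }
    cache$enc[[l]] <- cc
  }
  for (l in rev(seq_len(L - 1))) {
    cc <- list()
    cc$pre_up_dim <- dim(h)
    up <- upsample_fwd(h)
    cc$cu <- conv3_fwd(up, p[[sprintf("dec%d_Wu", l)]], p[[sprintf("dec%d_bu", l)]])
    cc$ru <- relu_fwd(cc$cu$out)
    skip <- cache$skips[[l]]
    cat3 <- array(c(skip, cc$ru$out),
                  c(dim(skip)[1], dim(skip)[2], dim(skip)[3] + dim(cc$ru$out)[3]))
    cc$skip_ch <- dim(skip)[3]
    cc$c1 <- conv3_fwd(cat3, p[[sprintf("dec%d_W1", l)]], p[[sprintf("dec%d_b1", l)]])
    cc$r1 <- relu_fwd(cc$c1$out)
    cc$c2 <- conv3_fwd(cc$r1$out, p[[sprintf("dec%d_W2", l)]], p[[sprintf("dec%d_b2", l)]])
    cc$r2 <- relu_fwd(cc$c2$out)
    h <- cc$r2$out
    cache$dec[[l]] <- cc
  }
  cache$pre_final <- h
  z <- conv1_fwd(h, p[["final_W"]], p[["final_b"]])
  list(probs = softmax3(z), cache = cache)
}

dim_at_level <- function(spec, l) {
  c(spec$input_shape / 2^(l - 1), spec$filters[l])
}

# Backward pass from the softmax + weighted cross-entropy gradient dZ
# (same shape as the logits). Returns named gradients for every parameter.
unet_backward <- function(model, dZ, cache) {
  spec <- model$spec
  p <- model$params
  L <- spec$levels
  g <- list()
  fb <- conv1_bwd(dZ, cache$pre_final, p[["final_W"]])
  g[["final_W"]] <- fb$dW; g[["final_b"]] <- fb$db
  dh <- fb$dX
  dskips <- vector("list", L)
  for (l in seq_len(L - 1)) {
    cc <- cache$dec[[l]]
    dh2 <- dh * cc$r2$mask
    b2 <- conv3_bwd(dh2, cc$c2$M, p[[sprintf("dec%d_W2", l)]],
                    cin = dim(cc$r1$out)[3])
    g[[sprintf("dec%d_W2", l)]] <- b2$dW; g[[sprintf("dec%d_b2", l)]] <- b2$db
    dh1 <- b2$dX * cc$r1$mask
    ncat <- cc$skip_ch + dim(cc$ru$out)[3]
    b1 <- conv3_bwd(dh1, cc$c1$M, p[[sprintf("dec%d_W1", l)]], cin = ncat)
    g[[sprintf("dec%d_W1", l)]] <- b1$dW; g[[sprintf("dec%d_b1", l)]] <- b1$db
    dskips[[l]] <- b1$dX[, , seq_len(cc$skip_ch), drop = FALSE]
    dru <- b1$dX[, , cc$skip_ch + seq_len(dim(cc$ru$out)[3]), drop = FALSE]
    dcu <- dru * cc$ru$mask
    up_ch <- cc$pre_up_dim[3]
    bu <- conv3_bwd(dcu, cc$cu$M, p[[sprintf("dec%d_Wu", l)]], cin = up_ch)
    g[[sprintf("dec%d_Wu", l)]] <- bu$dW; g[[sprintf("dec%d_bu", l)]] <- bu$db
    dh <- upsample_bwd(bu$dX)
  }
  # dh now holds the gradient at the bottleneck output; encoder backward,
  # deepest level first, adding each level's skip-connection gradient.
  for (l in rev(seq_len(L))) {
    cc <- cache$enc[[l]]
    if (l < L) {
      dpool <- maxpool_bwd(dh, cc$pool, cc$pre_pool_dim)
      dh <- dpool + dskips[[l]]
    }
    if (!is.null(cc$drop)) dh <- dh * cc$drop
    dh2 <- dh * cc$r2$mask
    b2 <- conv3_bwd(dh2, cc$c2$M, p[[sprintf("enc%d_W2", l)]],
                    cin = dim(cc$r1$out)[3])
    g[[sprintf("enc%d_W2", l)]] <- b2$dW; g[[sprintf("enc%d_b2", l)]] <- b2$db
    dh1 <- b2$dX * cc$r1$mask
    cin <- if (l == 1) 1L else spec$filters[l - 1]
    b1 <- conv3_bwd(dh1, cc$c1$M, p[[sprintf("enc%d_W1", l)]], cin = cin)
    g[[sprintf("enc%d_W1", l)]] <- b1$dW; g[[sprintf("enc%d_b1", l)]] <- b1$db
    dh <- b1$dX
  }
  g
}

# ---- training ---------------------------------------------------------------

#' Training configuration for the U-Net segmenter
#'
#' @param learning_rate Adam step size (default 1e-5; the desk-scale phantom
#'   profile uses 1e-3, see [train_unet()]).
#' @param epochs Training epochs (default 30).
#' @param batch_size Images per Adam update (default 1).
#' @param folds Number of subject-level cross-validation folds (default 5).
#' @param augmentation_factor Training-set multiplication by random elastic
#'   deformation; 10 gives nine deformed copies per image (default 10).
#' @param seed Master seed for initialisation, shuffling, dropout and
#'   augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, epochs = 30, batch_size = 1,
                         folds = 5, augmentation_factor = 10, seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1, folds >= 1,
            augmentation_factor >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 folds = as.integer(folds),
                 augmentation_factor = as.integer(augmentation_factor),
                 seed = as.integer(seed)), class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

one_hot_mask <- function(mask, classes = 2) {
  y <- array(0, c(dim(mask), classes))
  y[, , 1] <- !mask
  y[, , 2] <- mask
  y
}

#' Fit the U-Net on a set of image/mask pairs
#'
#' Per-image Adam updates on the weighted categorical cross-entropy; class
#' weights are computed from the training masks. Aborts with diagnostics if
#' the loss diverges to NaN.
#'
#' @param model A [unet_init()] model.
#' @param images List of intensity matrices (0-255).
#' @param masks List of logical lumen masks.
#' @param config A [train_config()] (folds/augmentation fields are ignored
#'   here; see [train_unet()] for the cross-validated driver).
#' @return The model with trained parameters; `$history` holds the mean
#'   epoch loss.
#' @export
unet_fit <- function(model, images, masks, config = train_config()) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  n_bg <- sum(vapply(masks, function(m) sum(!m), numeric(1)))
  n_fg <- sum(vapply(masks, function(m) sum(m), numeric(1)))
  w <- class_weights(c(n_bg, n_fg))
  ys <- lapply(masks, one_hot_mask, classes = model$spec$classes)
  state <- adam_init(model$params)
  history <- numeric(config$epochs)
  npix <- prod(model$spec$input_shape)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(config$seed * 1000 + ep, sample(seq_along(images)))
    ep_loss <- 0
    acc <- NULL; acc_n <- 0L
    for (i in ord) {
      fw <- unet_forward(model, images[[i]], training = TRUE,
                         dropout_seed = config$seed + 7919L * ep + i)
      y <- ys[[i]]
      loss <- weighted_cce(y, fw$probs, w)
      if (!is.finite(loss))
        stop_detrusor(sprintf("training diverged (non-finite loss, epoch %d)", ep))
      ep_loss <- ep_loss + loss
      wmap <- array(w[1] * (y[, , 1] == 1) + w[2] * (y[, , 2] == 1),
                    dim(fw$probs))
      dZ <- (fw$probs - y) * wmap / npix
      g <- unet_backward(model, dZ, fw$cache)
      if (is.null(acc)) acc <- g
      else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
      acc_n <- acc_n + 1L
      if (acc_n == config$batch_size) {
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / acc_n
        upd <- adam_step(model$params, acc, state, config$learning_rate)
        model$params <- upd$params; state <- upd$state
        acc <- NULL; acc_n <- 0L
      }
    }
    if (acc_n > 0) {
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / acc_n
      upd <- adam_step(model$params, acc, state, config$learning_rate)
      model$params <- upd$params; state <- upd$state
      acc <- NULL; acc_n <- 0L
    }
    history[ep] <- ep_loss / length(images)
  }
  model$history <- history
  model$class_weights <- w
  model
}

#' Predict a binary segmentation mask
#'
#' Softmax forward pass and per-pixel argmax.
#'
#' @param model A trained `unet_model`.
#' @param image Intensity matrix (0-255) of the model's input shape.
#' @return Logical mask (foreground = bladder).
#' @export
unet_predict <- function(model, image) {
  if (!all(dim(image) == model$spec$input_shape))
    stop_detrusor("image shape does not match the model input shape")
  fw <- unet_forward(model, image, training = FALSE)
  fw$probs[, , 2] > fw$probs[, , 1]
}

#' Train the U-Net with subject-level cross-validation
#'
#' Splits images into subject-level folds, optionally multiplies the
#' training split by random elastic deformation, fits one model per
#' requested fold and reports the held-out Dice of each.
#'
#' @param images List of intensity matrices.
#' @param masks List of logical masks.
#' @param subject_ids Per-image subject identifiers.
#' @param spec A [unet_spec()].
#' @param config A [train_config()].
#' @param folds_to_run Which folds to train (default all); training one fold
#'   gives a single held-out estimate at a fraction of the cost.
#' @return A list with `fold_dice` (tibble: fold, mean validation Dice),
#'   `models` (per trained fold), `fold_assignment`, and `manifest`
#'   (tibble of the training instances of the last trained fold, recording
#'   augmentation provenance).
#' @export
train_unet <- function(images, masks, subject_ids, spec = unet_spec(),
                       config = train_config(), folds_to_run = NULL) {
  stopifnot(length(images) == length(masks),
            length(images) == length(subject_ids))
  fold_of <- subject_folds(subject_ids, config$folds, seed = config$seed)
  if (is.null(folds_to_run)) folds_to_run <- seq_len(config$folds)
  fold_dice <- list(); models <- list(); manifest <- NULL
  for (f in folds_to_run) {
    tr <- which(fold_of != f); va <- which(fold_of == f)
    tr_img <- images[tr]; tr_msk <- masks[tr]
    man <- tibble::tibble(instance = seq_along(tr), source = tr,
                          deformed = FALSE)
    if (config$augmentation_factor > 1) {
      for (rep_i in seq_len(config$augmentation_factor - 1)) {
        for (j in seq_along(tr)) {
          aug <- elastic_augment(images[[tr[j]]], masks[[tr[j]]],
                                 seed = config$seed + 131L * rep_i + tr[j])
          tr_img[[length(tr_img) + 1]] <- aug$image
          tr_msk[[length(tr_msk) + 1]] <- aug$mask
          man <- dplyr::bind_rows(man, tibble::tibble(
            instance = length(tr_img), source = tr[j], deformed = TRUE))
        }
      }
    }
    model <- unet_init(spec, seed = config$seed + f)
    model <- unet_fit(model, tr_img, tr_msk, config)
    dices <- vapply(va, function(i)
      dice(unet_predict(model, images[[i]]), masks[[i]]), numeric(1))
    fold_dice[[length(fold_dice) + 1]] <-
      tibble::tibble(fold = f, dice = mean(dices), n_val = length(va))
    models[[as.character(f)]] <- model
    manifest <- man
  }
  list(fold_dice = dplyr::bind_rows(fold_dice), models = models,
       fold_assignment = fold_of, manifest = manifest)
}
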