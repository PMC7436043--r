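# Loss, augmentation, folds and the convolutional segmenter.

test_that("class weights balance by the majority count", {
  expect_equal(class_weights(c(50, 50)), c(1, 1))
  expect_equal(class_weights(c(90, 10)), c(1, 9))
  expect_equal(class_weights(100), 1)
  expect_error(class_weights(c(10, 0)), "positive")
})

test_that("weighted cross-entropy matches hand arithmetic and reduces", {
  y <- rbind(c(1, 0), c(0, 1))
  yhat <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  expect_equal(weighted_cce(y, yhat, c(1, 2)),
               (-log(0.8) - 2 * log(0.6)) / 2)
  # unit weights equal the unweighted categorical cross-entropy
  expect_equal(weighted_cce(y, yhat, c(1, 1)),
               mean(-rowSums(y * log(yhat))))
  expect_equal(weighted_cce(y, yhat), weighted_cce(y, yhat, c(1, 1)))
  # perfect one-hot predictions cost (numerically) nothing
  expect_lt(weighted_cce(y, y, c(1, 3)), 1e-5)
  expect_error(weighted_cce(y, yhat[1, , drop = FALSE]), "shapes")
})

test_that("elastic deformation is seeded, smooth and identity at zero", {
  ph <- unet_phantoms(1, seed = 3)$samples[[1]]
  img <- ph$image$pixels; msk <- ph$lumen_mask
  id <- elastic_augment(img, msk, magnitude_px = 0)
  expect_identical(id$image, img)
  a <- elastic_augment(img, msk, seed = 5)
  b <- elastic_augment(img, msk, seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  # default magnitude keeps most of the mask overlap and its topology
  expect_gte(dice(a$mask, msk), 0.8)
  lab <- EBImage::bwlabel(matrix(as.numeric(a$mask), nrow(a$mask)))
  expect_equal(max(lab), 1)
})

test_that("folds partition subjects, never images", {
  ids <- rep(sprintf("s%02d", 1:11), each = 4)
  f <- subject_folds(ids, 5, seed = 2)
  tab <- table(attr(f, "subjects")$fold)
  expect_equal(sort(as.integer(tab), decreasing = TRUE), c(3, 2, 2, 2, 2))
  # all images of a subject share a fold
  expect_true(all(tapply(f, ids, function(v) length(unique(v))) == 1))
  expect_equal(unique(subject_folds(ids, 1)), 1L)
  expect_error(subject_folds(c("a", "b", "c"), 5), "fewer")
})

test_that("backpropagated gradients match finite differences", {
  spec <- unet_spec(c(8, 8), base_filters = 2, levels = 2, dropout_rate = 0)
  model <- unet_init(spec, seed = 4)
  img <- matrix(runif(64, 0, 255), 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  y <- array(0, c(8, 8, 2)); y[, , 1] <- !mask; y[, , 2] <- mask
  w <- c(1, 1.7)
  loss_at <- function(m) {
    fw <- detrusor:::unet_forward(m, img)
    weighted_cce(y, fw$probs, w)
  }
  fw <- detrusor:::unet_forward(model, img)
  wmap <- array(w[1] * (y[, , 1] == 1) + w[2] * (y[, , 2] == 1), dim(fw$probs))
  dZ <- (fw$probs - y) * wmap / 64
  g <- detrusor:::unet_backward(model, dZ, fw$cache)
  eps <- 1e-5
  set.seed(9)
  for (nm in c("enc1_W1", "enc2_W2", "dec1_Wu", "dec1_W1", "final_W",
               "enc1_b2", "dec1_b2", "final_b")) {
    p <- model$params[[nm]]
    for (k in sample(length(p), min(3, length(p)))) {
      m2 <- model; m2$params[[nm]][k] <- p[k] + eps
      m3 <- model; m3$params[[nm]][k] <- p[k] - eps
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      expect_equal(g[[nm]][k], num, tolerance = 1e-4)
    }
  }
})

test_that("training machinery respects shapes, counting and divergence", {
  spec <- unet_spec(c(16, 16), base_filters = 2, levels = 3)
  model <- unet_init(spec, seed = 1)
  img <- matrix(runif(256, 0, 255), 16, 16)
  expect_error(unet_predict(model, matrix(0, 8, 8)), "shape")
  expect_true(is.logical(unet_predict(model, img)))
  expect_error(unet_spec(c(60, 80)), "divisible")

  # augmentation multiplies the training manifest
  ds <- unet_phantoms(8, seed = 6)
  imgs <- lapply(ds$samples, function(s) s$image$pixels)
  msks <- lapply(ds$samples, function(s) s$lumen_mask)
  res <- train_unet(imgs, msks, ds$manifest$subject_id,
                    spec = unet_spec(c(64, 80), base_filters = 2),
                    config = train_config(epochs = 0, folds = 2,
                                          augmentation_factor = 3),
                    folds_to_run = 1)
  n_tr <- sum(res$fold_assignment != 1)
  expect_equal(nrow(res$manifest), 3 * n_tr)
  expect_equal(sum(res$manifest$deformed), 2 * n_tr)
})

test_that("a short fit reduces the loss on its training split", {
  ds <- unet_phantoms(6, seed = 8)
  imgs <- lapply(ds$samples, function(s) s$image$pixels)
  msks <- lapply(ds$samples, function(s) s$lumen_mask)
  model <- unet_init(unet_spec(c(64, 80), base_filters = 4), seed = 2)
  fit <- unet_fit(model, imgs, msks,
                  train_config(learning_rate = 1e-3, epochs = 6))
  expect_lt(fit$history[6], fit$history[1])
})
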