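# Fold construction, augmentation and the training loop.

test_that("make_folds partitions ids with balanced sizes, deterministically", {
  ids <- sprintf("s%03d", 1:175)
  folds <- make_folds(ids, 5, seed = 3)
  expect_length(folds, 5L)
  expect_true(all(vapply(folds, function(f) length(f$val_ids), 1L) == 35L))
  expect_setequal(unlist(lapply(folds, `[[`, "val_ids")), ids)
  expect_equal(sum(lengths(lapply(folds, `[[`, "val_ids"))), 175L)
  for (f in folds) expect_length(intersect(f$train_ids, f$val_ids), 0L)

  folds2 <- make_folds(ids, 5, seed = 3)
  expect_identical(folds, folds2)
  # uneven split: sizes differ by at most one
  f7 <- make_folds(ids[1:23], 4, seed = 1)
  expect_setequal(lengths(lapply(f7, `[[`, "val_ids")), c(6, 6, 6, 5))
  expect_error(make_folds(ids[1:3], 5, seed = 1), "exceeds")
})

test_that("augmentation at probability zero is the identity", {
  s <- tiny_scene(seed = 1)
  hm <- points_to_heatmap(s$points, dim(s$image)[1:2])
  a <- augment_sample(s$image, hm, augmentation_config(probability = 0))
  expect_identical(a$image, s$image)
  expect_identical(a$heatmap, hm)
})

test_that("flips are involutions and quarter turns move the argmax correctly", {
  s <- tiny_scene(seed = 2)
  img <- s$image
  flip_v <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  expect_identical(flip_v(flip_v(img)), img)

  # single-point heatmap so the argmax is unique
  hm <- points_to_heatmap(s$points[1, , drop = FALSE], dim(s$image)[1:2])
  n <- nrow(hm)
  rot90 <- function(m) t(m)[n:1, ]     # one quarter turn
  am0 <- which(hm == max(hm), arr.ind = TRUE)[1, ]
  hm90 <- rot90(hm)
  am90 <- which(hm90 == max(hm90), arr.ind = TRUE)[1, ]
  # coordinate-map oracle: (r, c) -> (n + 1 - c, r)
  expect_equal(unname(am90), unname(c(n + 1 - am0[2], am0[1])))
})

test_that("free rotation keeps heatmap peaks aligned with rotated points", {
  s <- tiny_scene(seed = 3, n_spots = 6L)
  hm <- points_to_heatmap(s$points, dim(s$image)[1:2])
  theta <- 12 * pi / 180
  hm_rot <- fungiform:::rotate_array(array(hm, dim = c(dim(hm), 1L)), theta,
                                     pad = "zero")[, , 1]
  want <- fungiform:::rotate_points(s$points, theta, dim(hm))
  got <- detect_peaks(pmin(pmax(hm_rot, 0), 1), heatmap_config())
  keep <- want[, 1] > 10 & want[, 1] < 117 & want[, 2] > 10 & want[, 2] < 117
  oc <- match_points(want[keep, , drop = FALSE], got, radius = 1.5)
  expect_equal(oc$un, 0L)  # every rotated annotation has a peak within 1.5 px
})

test_that("augmented pairs stay geometrically consistent end to end", {
  set.seed(42)
  s <- tiny_scene(seed = 4, n_spots = 8L)
  hm <- points_to_heatmap(s$points, dim(s$image)[1:2])
  for (rep in 1:5) {
    a <- augment_sample(s$image, hm, augmentation_config(probability = 1))
    expect_equal(dim(a$image)[1:2], dim(a$heatmap))
    expect_true(all(a$heatmap >= 0 & a$heatmap <= 1))
    expect_true(all(a$image >= 0 & a$image <= 1))
    if (max(a$heatmap) > 0.5) {
      # peaks of the augmented heatmap coincide with bright spots of the
      # augmented image (joint geometry): at the global argmax the image must
      # be brighter than its immediate surroundings inside the stain
      am <- which(a$heatmap == max(a$heatmap), arr.ind = TRUE)[1, ]
      lum <- 0.299 * a$image[, , 1] + 0.587 * a$image[, , 2] + 0.114 * a$image[, , 3]
      ri <- max(1, am[1] - 2):min(128, am[1] + 2)
      ci <- max(1, am[2] - 2):min(128, am[2] + 2)
      ro <- max(1, am[1] - 8):min(128, am[1] + 8)
      co <- max(1, am[2] - 8):min(128, am[2] + 8)
      ring <- lum[ro, co]
      expect_gt(mean(lum[ri, ci]),
                (sum(ring) - sum(lum[ri, ci])) / (length(ring) - length(ri) * length(ci)))
    }
  }
})

test_that("the training loop records history and enforces its contracts", {
  expect_error(training_config(epochs = 0))
  spec <- optimized_unet_spec(3L, dropout_rate = 0.1, width_scale = 0.05)
  set.seed(1)
  pairs <- lapply(1:4, function(i) {
    list(image = array(runif(32 * 32 * 3), dim = c(32, 32, 3)),
         heatmap = points_to_heatmap(c(15, 15), c(32, 32), heatmap_config(sigma = 2)))
  })
  cfg <- training_config(epochs = 1, batch_size = 2, seed = 9)
  m <- train_model(spec, pairs[1:3], pairs[4], cfg)
  expect_equal(nrow(m$history), 1L)
  expect_true(all(is.finite(unlist(m$history))))
  expect_true(m$trained)

  # a divergent learning rate overflows the weights and aborts with the epoch
  cfg_bad <- training_config(epochs = 4, batch_size = 2, learning_rate = 1e300,
                             seed = 9)
  expect_error(train_model(spec, pairs[1:3], NULL, cfg_bad),
               "non-finite training loss at epoch")
})

test_that("cross-validation trains one model per fold on disjoint splits", {
  spec <- optimized_unet_spec(3L, dropout_rate = 0, width_scale = 0.05)
  set.seed(2)
  samples <- lapply(1:6, function(i) {
    img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
    fp_sample(img, c(16, 16), sample_id = paste0("s", i))
  })
  cfg <- training_config(k_folds = 3, epochs = 1, batch_size = 2, seed = 5)
  cv <- run_cross_validation(spec, samples, cfg, heatmap_config(sigma = 2))
  expect_length(cv, 3L)
  val_ids <- unlist(lapply(cv, function(r) r$split$val_ids))
  expect_setequal(val_ids, 1:6)
  expect_length(val_ids, 6L)
  for (r in cv) expect_equal(nrow(r$history), 1L)
  # fold assignment is reproducible under the master seed
  cv2 <- run_cross_validation(spec, samples, cfg, heatmap_config(sigma = 2))
  expect_identical(lapply(cv, function(r) r$split), lapply(cv2, function(r) r$split))
})

test_that("validation samples never enter the training batches", {
  # id-level bookkeeping: folds are disjoint by construction, and train_model
  # only ever indexes the train split
  folds <- make_folds(1:20, 4, seed = 8)
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$val_ids), 0L)
    expect_setequal(c(f$train_ids, f$val_ids), 1:20)
  }
})
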