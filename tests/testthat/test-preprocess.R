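# Stain-ellipse detection, cropping, resizing and CLAHE.

render_ellipse_image <- function(center, a, b, theta, shape = c(256, 256)) {
  rows <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  dr <- rows - center[1]; dc <- cols - center[2]
  u <- dr * sin(theta) + dc * cos(theta)
  v <- dr * cos(theta) - dc * sin(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  img <- array(0, dim = c(shape, 3))
  img[, , 1] <- ifelse(inside, 0.2, 0.8)
  img[, , 2] <- 0.5
  img[, , 3] <- ifelse(inside, 0.8, 0.2)
  img
}

test_that("a rendered disk is recovered within a pixel", {
  img <- render_ellipse_image(c(120, 130), 80, 80, 0)
  ell <- detect_ellipse(img)
  expect_lt(max(abs(ell$center - c(120, 130))), 1)
  expect_lt(max(abs(ell$semi_axes - 80)), 2)
})

test_that("an oriented ellipse is recovered within 3 percent", {
  img <- render_ellipse_image(c(128, 128), 90, 60, 0.4)
  ell <- detect_ellipse(img)
  expect_lt(max(abs(ell$center - 128)), 2)
  expect_lt(abs(ell$semi_axes[1] - 90) / 90, 0.03)
  expect_lt(abs(ell$semi_axes[2] - 60) / 60, 0.03)
  expect_lt(abs(ell$orientation - 0.4), 0.03)
})

test_that("images without a stained region raise a detection error", {
  flat <- array(0.5, dim = c(64, 64, 3))
  expect_error(detect_ellipse(flat), "no stain")
  # a stained speck below 1% of the image area is not a region
  speck <- array(0, dim = c(64, 64, 3))
  speck[, , 1] <- 0.8; speck[32, 32, ] <- c(0.2, 0.5, 0.8)
  expect_error(detect_ellipse(speck), "no stain")
})

test_that("crop_square computes side, offset and transform", {
  img <- array(0.5, dim = c(300, 300, 3))
  ell <- list(center = c(100, 100), semi_axes = c(50, 50), orientation = 0)
  cr <- crop_square(img, ell, margin = 0)
  expect_equal(dim(cr$image)[1:2], c(100, 100))
  expect_equal(cr$transform$crop_offset, c(50, 50))

  cr2 <- crop_square(img, ell, margin = 0.1)
  expect_equal(dim(cr2$image)[1], 110)

  # near the border the window is shifted, stays square, transform consistent
  ell_b <- list(center = c(10, 10), semi_axes = c(50, 50), orientation = 0)
  cr3 <- crop_square(img, ell_b, margin = 0)
  expect_equal(dim(cr3$image)[1:2], c(100, 100))
  expect_equal(cr3$transform$crop_offset, c(0, 0))
  # a point at the original origin maps to the crop origin
  expect_equal(as.numeric(transform_points(c(0, 0), cr3$transform)), c(0, 0))

  expect_error(crop_square(img, list(semi_axes = c(0, 0), center = c(5, 5))),
               "degenerate")
})

test_that("resize_to_standard rescales squares bilinearly", {
  cfg <- preprocess_config(target_side = 250)
  img <- array(runif(500 * 500 * 3), dim = c(500, 500, 3))
  rs <- resize_to_standard(img, cfg)
  expect_equal(dim(rs$image)[1:2], c(250, 250))
  expect_equal(rs$transform$scale, c(0.5, 0.5))

  same <- resize_to_standard(array(0.3, dim = c(250, 250, 3)), cfg)
  expect_equal(same$transform$scale, c(1, 1))

  const <- resize_to_standard(array(0.7, dim = c(100, 100, 3)), cfg)
  expect_equal(range(const$image), c(0.7, 0.7), tolerance = 1e-12)

  expect_error(resize_to_standard(array(0.1, dim = c(100, 120, 3)), cfg), "square")
})

test_that("CLAHE keeps range, flattens constants and raises spot contrast", {
  cfg <- preprocess_config()
  const <- clahe_normalize(array(0.4, dim = c(64, 64, 3)), cfg)
  expect_equal(sd(const), 0)

  set.seed(8)
  noisy <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  out <- clahe_normalize(noisy, cfg)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)

  # low-contrast scene: spot-vs-background separation must strictly increase
  s <- generate_scene(scene_config(image_size = c(128, 128), n_spots = 12,
                                   spot_radius_px = c(2.5, 4.5),
                                   spot_contrast = c(0.08, 0.12),
                                   min_separation = 8, noise_sd = 0.005,
                                   seed = 21))
  lum <- function(img) 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  contrast <- function(img) {
    l <- lum(img)
    spot <- matrix(FALSE, nrow(l), ncol(l))
    for (k in seq_len(nrow(s$points)))
      spot[s$points[k, 1] + 1, s$points[k, 2] + 1] <- TRUE
    ell <- attr(s, "stain_ellipse")
    rows <- matrix(seq_len(nrow(l)) - 1, nrow(l), ncol(l))
    cols <- matrix(seq_len(ncol(l)) - 1, nrow(l), ncol(l), byrow = TRUE)
    inside <- ((rows - ell$center[1]) / ell$semi_axes[1])^2 +
              ((cols - ell$center[2]) / ell$semi_axes[2])^2 <= 0.8^2
    mean(l[spot]) - mean(l[inside & !spot])
  }
  expect_gt(contrast(clahe_normalize(s$image, cfg)), contrast(s$image))
})

test_that("the full chain yields aligned standard-size annotated samples", {
  s <- generate_scene(scene_config(n_spots = 15, seed = 33))
  cfg <- preprocess_config()
  out <- preprocess_sample(s, cfg)
  expect_equal(dim(out$image)[1:2], c(250, 250))
  expect_equal(nrow(out$points), 15)
  expect_equal(length(out$transforms), 2L)

  # determinism
  out2 <- preprocess_sample(s, cfg)
  expect_identical(out$image, out2$image)
  expect_identical(out$points, out2$points)

  # alignment: each mapped annotation sits within 2 px of a local brightness
  # maximum of the processed image (spots are the brightest local structure)
  lum <- 0.299 * out$image[, , 1] + 0.587 * out$image[, , 2] + 0.114 * out$image[, , 3]
  for (k in seq_len(nrow(out$points))) {
    r <- round(out$points[k, 1]) + 1; c <- round(out$points[k, 2]) + 1
    ri <- max(1, r - 4):min(250, r + 4)
    ci <- max(1, c - 4):min(250, c + 4)
    win <- lum[ri, ci]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    peak_abs <- c(ri[peak[1]], ci[peak[2]])
    expect_lte(max(abs(peak_abs - c(r, c))), 2.5)
  }
})

test_that("annotations outside the crop are dropped and logged", {
  # small stain ellipse in a large frame with one far-away annotation
  img <- render_ellipse_image(c(128, 128), 60, 50, 0.2)
  s <- fp_sample(img, rbind(c(128, 128), c(5, 5)), sample_id = "drop_case")
  out <- preprocess_sample(s, preprocess_config())
  expect_equal(nrow(out$points), 1L)
  expect_equal(out$n_dropped, 1L)
})
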