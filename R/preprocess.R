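# Preprocessing chain: stain-ellipse detection -> square crop -> resize to
# the standard working resolution -> CLAHE contrast normalization.
# Annotations are carried through each geometric stage analytically.

#' Preprocessing settings
#'
#' @param target_side Output resolution in pixels (square), default 250.
#' @param crop_margin Fractional margin added around the stain ellipse.
#' @param clahe_clip_limit CLAHE contrast clip limit.
#' @param clahe_tile_grid `(rows, cols)` CLAHE tile grid.
#' @param clahe_channels Apply CLAHE to the `"luminance"` channel (default)
#'   or to each color channel independently (`"per_channel"`).
#' @param stain_channel_weights Length-3 projection picking out the stain
#'   color; the default (blue minus red) responds to the blue food dye.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_side = 250L, crop_margin = 0.05,
                              clahe_clip_limit = 2, clahe_tile_grid = c(8L, 8L),
                              clahe_channels = c("luminance", "per_channel"),
                              stain_channel_weights = c(-1, 0, 1)) {
  clahe_channels <- match.arg(clahe_channels)
  stopifnot(target_side >= 32, clahe_clip_limit > 0,
            length(clahe_tile_grid) == 2, length(stain_channel_weights) == 3)
  structure(list(target_side = as.integer(target_side),
                 crop_margin = crop_margin,
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 clahe_channels = clahe_channels,
                 stain_channel_weights = stain_channel_weights),
            class = "preprocess_config")
}

#' Detect the stained elliptical region
#'
#' Projects the image onto the stain color axis, thresholds by Otsu's method,
#' cleans the mask by morphological closing, keeps the largest connected
#' component and fits an ellipse from its second-order moments (for a filled
#' ellipse the semi-axes are twice the standard deviations along the
#' principal directions).
#'
#' @param image 3-channel image array.
#' @param config A [preprocess_config()].
#' @return List with `center` `(row, col)`, `semi_axes` `(a, b)` with
#'   `a >= b`, and `orientation` (radians; angle of the major axis measured
#'   from the column axis toward the row axis, modulo pi).
#' @export
detect_ellipse <- function(image, config = preprocess_config()) {
  image <- as_image_array(image)
  if (dim(image)[3] != 3L) stop("ellipse detection needs a 3-channel image")
  w <- config$stain_channel_weights
  proj <- image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3]
  rng <- range(proj)
  if (diff(rng) < 1e-8) stop("no stain-consistent region found (flat image)")
  proj <- (proj - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(t(proj)))
  mask <- proj > thr
  mask_img <- EBImage::closing(EBImage::Image(t(mask)),
                               EBImage::makeBrush(5, shape = "disc"))
  labels <- t(EBImage::imageData(EBImage::bwlabel(mask_img)))
  if (max(labels) < 1) stop("no stain-consistent region found")
  sizes <- tabulate(labels[labels > 0])
  big <- which.max(sizes)
  if (sizes[big] < 0.01 * length(proj))
    stop("no stain-consistent region found (largest component < 1% of image)")
  idx <- which(labels == big, arr.ind = TRUE)
  pr <- idx[, 1] - 1; pc <- idx[, 2] - 1
  center <- c(mean(pr), mean(pc))
  cv <- stats::cov(cbind(pr, pc)) * (length(pr) - 1) / length(pr)
  eg <- eigen(cv, symmetric = TRUE)
  a <- 2 * sqrt(max(eg$values[1], 0))
  b <- 2 * sqrt(max(eg$values[2], 0))
  v <- eg$vectors[, 1]
  list(center = center, semi_axes = c(a, b),
       orientation = atan2(v[1], v[2]) %% pi)
}

#' Crop a square region around the stain ellipse
#'
#' The square side is `2 (1 + margin) max(a, b)`, clamped to the image; the
#' window is centered on the ellipse and shifted (not shrunk) when it
#' overruns a border, so the output is always square.
#'
#' @param image Image array.
#' @param ellipse Ellipse as returned by [detect_ellipse()].
#' @param margin Fractional margin (default from the standard chain, 0.05).
#' @return List `image` (cropped array) and `transform` (an [fp_transform()]
#'   mapping original to cropped coordinates).
#' @export
crop_square <- function(image, ellipse, margin = 0.05) {
  image <- as_image_array(image)
  d <- dim(image)
  ax <- ellipse$semi_axes
  if (any(!is.finite(ax)) || any(ax <= 0)) stop("degenerate ellipse")
  side <- round(2 * (1 + margin) * max(ax))
  side <- min(side, d[1], d[2])
  if (side < 2) stop("degenerate ellipse (crop side < 2 px)")
  r0 <- round(ellipse$center[1] - side / 2)
  c0 <- round(ellipse$center[2] - side / 2)
  r0 <- min(max(r0, 0), d[1] - side)
  c0 <- min(max(c0, 0), d[2] - side)
  list(image = image[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE],
       transform = fp_transform(crop_offset = c(r0, c0)))
}

# bilinear sampling of an (H,W,C) array at fractional (row, col) positions;
# out-of-range positions are clamped (border replication)
bilinear_sample <- function(img, r, c) {
  d <- dim(img)
  r <- pmin(pmax(r, 0), d[1] - 1)
  c <- pmin(pmax(c, 0), d[2] - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, d[1] - 1); c1 <- pmin(c0 + 1, d[2] - 1)
  fr <- r - r0; fc <- c - c0
  out <- array(0, dim = c(length(r), 1, d[3]))
  dim(out) <- c(length(r), d[3])
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    out[, ch] <-
      m[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
      m[cbind(r1 + 1, c0 + 1)] * fr * (1 - fc) +
      m[cbind(r0 + 1, c1 + 1)] * (1 - fr) * fc +
      m[cbind(r1 + 1, c1 + 1)] * fr * fc
  }
  out
}

# bilinear resize of an (H,W,C) array to (rows, cols)
bilinear_resize <- function(img, rows, cols) {
  d <- dim(img)
  sr <- rows / d[1]; sc <- cols / d[2]
  rr <- ((seq_len(rows) - 0.5) / sr) - 0.5
  cc <- ((seq_len(cols) - 0.5) / sc) - 0.5
  grid_r <- rep(rr, times = cols)
  grid_c <- rep(cc, each = rows)
  out <- bilinear_sample(img, grid_r, grid_c)
  array(out, dim = c(rows, cols, d[3]))
}

#' Resize a square image to the standard resolution
#'
#' Bilinear interpolation; the returned transform maps original-pixel
#' coordinates to resized coordinates (`p * s - (s - 1)/2`, pixel centers at
#' integers), so point annotations are rescaled analytically rather than
#' resampled.
#'
#' @param image Square image array.
#' @param config A [preprocess_config()].
#' @return List `image`, `transform`.
#' @export
resize_to_standard <- function(image, config = preprocess_config()) {
  image <- as_image_array(image)
  d <- dim(image)
  if (d[1] != d[2]) stop("resize_to_standard expects a square input")
  ts <- config$target_side
  s <- ts / d[1]
  tr <- fp_transform(crop_offset = c(-(s - 1) / (2 * s), -(s - 1) / (2 * s)),
                     scale = c(s, s))
  if (d[1] == ts) return(list(image = image, transform = fp_transform()))
  list(image = pmin(pmax(bilinear_resize(image, ts, ts), 0), 1), transform = tr)
}

# CLAHE on a single-channel matrix via EBImage (which is x-major); the
# implementation needs dimensions divisible by the tile grid, so the matrix
# is reflection-padded up to the next multiple and cropped back
clahe_matrix <- function(m, config) {
  d <- dim(m)
  ny <- config$clahe_tile_grid[1]; nx <- config$clahe_tile_grid[2]
  ph <- (ny - d[1] %% ny) %% ny
  pw <- (nx - d[2] %% nx) %% nx
  ri <- c(seq_len(d[1]), rev(seq_len(d[1]))[seq_len(ph)])
  ci <- c(seq_len(d[2]), rev(seq_len(d[2]))[seq_len(pw)])
  mp <- m[ri, ci, drop = FALSE]
  res <- EBImage::clahe(EBImage::Image(t(mp)), nx = nx, ny = ny,
                        limit = config$clahe_clip_limit)
  t(EBImage::imageData(res))[seq_len(d[1]), seq_len(d[2])]
}

#' CLAHE contrast normalization
#'
#' Contrast Limited Adaptive Histogram Equalization, enhancing local contrast
#' so papillae remain visible under uneven staining and illumination. For
#' color images the default equalizes the luminance channel and rescales the
#' color channels proportionally, preserving hue.
#'
#' @param image Image array in `[0,1]`.
#' @param config A [preprocess_config()].
#' @return Image array in `[0,1]` of the same shape.
#' @export
clahe_normalize <- function(image, config = preprocess_config()) {
  image <- as_image_array(image)
  d <- dim(image)
  if (d[3] == 1L || config$clahe_channels == "per_channel") {
    out <- image
    for (ch in seq_len(d[3])) out[, , ch] <- clahe_matrix(image[, , ch], config)
  } else {
    lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    lum2 <- clahe_matrix(lum, config)
    ratio <- (lum2 + 1e-6) / (lum + 1e-6)
    out <- image
    for (ch in 1:3) out[, , ch] <- image[, , ch] * ratio
  }
  pmin(pmax(out, 0), 1)
}

#' Run the full preprocessing chain on an annotated sample
#'
#' Ellipse detection, square crop, resize to the standard resolution and
#' CLAHE, with annotations mapped through the composed geometric transform.
#' Annotations falling outside the crop are dropped and counted in the
#' result's `n_dropped` field.
#'
#' @param raw An [fp_sample()] with a 3-channel image.
#' @param config A [preprocess_config()].
#' @return A processed `fp_sample` of size `target_side x target_side`.
#' @export
preprocess_sample <- function(raw, config = preprocess_config()) {
  stopifnot(inherits(raw, "fp_sample"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("preprocess stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  ell <- stage("detect_ellipse", detect_ellipse(raw$image, config))
  cr <- stage("crop_square", crop_square(raw$image, ell, config$crop_margin))
  rs <- stage("resize_to_standard", resize_to_standard(cr$image, config))
  img <- stage("clahe_normalize", clahe_normalize(rs$image, config))

  p1 <- transform_points(raw$points, cr$transform, bounds = dim(cr$image)[1:2])
  p2 <- transform_points(p1, rs$transform, bounds = dim(img)[1:2])
  out <- fp_sample(img, p2, sample_id = raw$sample_id,
                   transforms = c(raw$transforms, list(cr$transform, rs$transform)))
  out$n_dropped <- attr(p1, "n_dropped") + attr(p2, "n_dropped")
  out
}
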