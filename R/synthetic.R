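# Synthetic stained-tongue scene generator.
#
# Emulates the photographic material the detector is meant for: a dark,
# blue-stained elliptical region on a lighter tongue surface, speckled inside
# with small darker filiform-papilla distractors, containing a known number
# of lighter, softly-shaded elliptical fungiform-papilla spots. Spot centers
# are the ground-truth annotations, so every pipeline stage can be tested
# against exact coordinates.

#' Scene configuration for the synthetic generator
#'
#' Defaults emulate the published imaging conditions at the standard 250x250
#' working resolution: papilla counts drawn from a truncated normal with mean
#' 16.96 and SD 7.67 (the study's observed counts), restricted to 5-40 per
#' region.
#'
#' @param image_size `(rows, cols)` in pixels.
#' @param n_spots Either a single count, a length-2 range `c(lo, hi)` sampled
#'   uniformly, or `NULL` for the truncated-normal count model.
#' @param spot_radius_px Range of spot Gaussian radii (pixels).
#' @param spot_eccentricity Range of major/minor axis ratios.
#' @param spot_contrast Range of peak intensity lift of a spot over the
#'   stained background, in intensity units.
#' @param min_separation Minimum center-to-center distance between spots.
#' @param background_speckle_density Expected filiform distractors per pixel
#'   of stained area.
#' @param stain_ellipse `"auto"` (random plausible ellipse) or a list with
#'   `center`, `semi_axes`, `orientation`.
#' @param illumination_gradient Amplitude of a linear illumination ramp.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param seed Integer seed; every scene is a pure function of its config.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = c(250L, 250L),
                         n_spots = NULL,
                         spot_radius_px = c(3.5, 6),
                         spot_eccentricity = c(1, 1.3),
                         spot_contrast = c(0.3, 0.55),
                         min_separation = 9,
                         background_speckle_density = 0.002,
                         stain_ellipse = "auto",
                         illumination_gradient = 0.06,
                         noise_sd = 0.01,
                         seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            diff(spot_radius_px) >= 0, diff(spot_contrast) >= 0,
            min_separation > 0, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size), n_spots = n_spots,
                 spot_radius_px = spot_radius_px,
                 spot_eccentricity = spot_eccentricity,
                 spot_contrast = spot_contrast,
                 min_separation = min_separation,
                 background_speckle_density = background_speckle_density,
                 stain_ellipse = stain_ellipse,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

# count model: truncated normal matching the study's observed counts
sample_spot_count <- function(n_spots) {
  if (is.null(n_spots)) {
    repeat {
      n <- round(stats::rnorm(1, mean = 16.96, sd = 7.67))
      if (n >= 5 && n <= 40) return(as.integer(n))
    }
  }
  if (length(n_spots) == 2) return(sample(n_spots[1]:n_spots[2], 1))
  as.integer(n_spots)
}

# base colors (RGB in [0,1]): lighter tongue surface, dark blue stain,
# lighter pink papilla tops, darker filiform speckle
.tongue_bg <- c(0.82, 0.60, 0.58)
.stain_col <- c(0.22, 0.26, 0.55)
.spot_col  <- c(0.88, 0.66, 0.68)

#' Generate one synthetic annotated tongue scene
#'
#' @param config A [scene_config()].
#' @return An [fp_sample()] whose `points` are the exact spot centers
#'   (integer pixel coordinates, emulating pixel-level manual clicks). The
#'   rendered stain ellipse is attached as attribute `"stain_ellipse"`.
#' @export
generate_scene <- function(config = scene_config()) {
  set.seed(config$seed)
  nr <- config$image_size[1]; nc <- config$image_size[2]
  rows <- matrix(seq_len(nr) - 1, nr, nc)
  cols <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)

  ell <- config$stain_ellipse
  if (identical(ell, "auto")) {
    a <- stats::runif(1, 0.34, 0.42) * min(nr, nc)
    ell <- list(center = c(nr / 2 + stats::runif(1, -0.03, 0.03) * nr,
                           nc / 2 + stats::runif(1, -0.03, 0.03) * nc),
                semi_axes = c(a, a * stats::runif(1, 0.8, 0.95)),
                orientation = stats::runif(1, 0, pi))
  }
  co <- cos(ell$orientation); si <- sin(ell$orientation)
  dr <- rows - ell$center[1]; dc <- cols - ell$center[2]
  u <- dr * si + dc * co   # along major axis
  v <- dr * co - dc * si   # along minor axis
  q <- (u / ell$semi_axes[1])^2 + (v / ell$semi_axes[2])^2
  inside <- q <= 1
  edge <- pmin(pmax((1.04 - q) / 0.08, 0), 1)  # soft stain boundary

  img <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3)
    img[, , ch] <- .tongue_bg[ch] + (.stain_col[ch] - .tongue_bg[ch]) * edge

  # filiform-papilla speckle: small darker blobs inside the stain
  n_spk <- stats::rpois(1, config$background_speckle_density * sum(inside))
  if (n_spk > 0) {
    in_idx <- which(inside)
    pos <- in_idx[sample.int(length(in_idx), min(n_spk, length(in_idx)))]
    spk_r <- (pos - 1) %% nr
    spk_c <- (pos - 1) %/% nr
    spk_amp <- stats::runif(length(pos), 0.05, 0.16)
    spk_sig <- stats::runif(length(pos), 0.8, 1.6)
    dark <- matrix(0, nr, nc)
    for (k in seq_along(pos)) {
      w <- ceiling(3 * spk_sig[k])
      ri <- max(0, spk_r[k] - w):min(nr - 1, spk_r[k] + w)
      ci <- max(0, spk_c[k] - w):min(nc - 1, spk_c[k] + w)
      g <- exp(-outer((ri - spk_r[k])^2, (ci - spk_c[k])^2, "+") / (2 * spk_sig[k]^2))
      dark[ri + 1, ci + 1] <- pmax(dark[ri + 1, ci + 1], spk_amp[k] * g)
    }
    for (ch in 1:3) img[, , ch] <- img[, , ch] - dark * edge
  }

  # fungiform spots: lighter anisotropic Gaussian profiles at integer centers
  n_spots <- sample_spot_count(config$n_spots)
  centers <- matrix(numeric(0), 0, 2)
  margin <- 0.82  # keep spots well inside the stain
  tries <- 0
  while (nrow(centers) < n_spots) {
    tries <- tries + 1
    if (tries > 4000 * n_spots)
      stop("spot placement infeasible: too many spots for the separation constraint")
    t <- stats::runif(1, 0, 2 * pi); rad <- sqrt(stats::runif(1))
    pu <- rad * cos(t) * ell$semi_axes[1] * margin
    pv <- rad * sin(t) * ell$semi_axes[2] * margin
    pr <- round(ell$center[1] + pu * si + pv * co)
    pc <- round(ell$center[2] + pu * co - pv * si)
    if (pr < 8 || pr > nr - 9 || pc < 8 || pc > nc - 9) next
    if (nrow(centers) &&
        min(sqrt((centers[, 1] - pr)^2 + (centers[, 2] - pc)^2)) < config$min_separation)
      next
    centers <- rbind(centers, c(pr, pc))
  }
  bright <- matrix(0, nr, nc)
  if (n_spots > 0) {
    for (k in seq_len(n_spots)) {
      sr <- stats::runif(1, config$spot_radius_px[1], config$spot_radius_px[2]) / 1.5
      ecc <- stats::runif(1, config$spot_eccentricity[1], config$spot_eccentricity[2])
      amp <- stats::runif(1, config$spot_contrast[1], config$spot_contrast[2])
      th <- stats::runif(1, 0, pi)
      w <- ceiling(3.5 * sr * ecc)
      ri <- max(0, centers[k, 1] - w):min(nr - 1, centers[k, 1] + w)
      ci <- max(0, centers[k, 2] - w):min(nc - 1, centers[k, 2] + w)
      rr <- outer(ri - centers[k, 1], rep(1, length(ci)))
      cc <- outer(rep(1, length(ri)), ci - centers[k, 2])
      uu <- rr * sin(th) + cc * cos(th)
      vv <- rr * cos(th) - cc * sin(th)
      g <- amp * exp(-0.5 * ((uu / (sr * ecc))^2 + (vv / sr)^2))
      bright[ri + 1, ci + 1] <- pmax(bright[ri + 1, ci + 1], g)
    }
  }
  for (ch in 1:3)
    img[, , ch] <- img[, , ch] +
      bright * edge * (.spot_col[ch] - .stain_col[ch]) / max(.spot_col - .stain_col)

  # illumination ramp and sensor noise
  if (config$illumination_gradient > 0) {
    th <- stats::runif(1, 0, 2 * pi)
    ramp <- (rows / nr) * cos(th) + (cols / nc) * sin(th)
    ramp <- config$illumination_gradient * (ramp - mean(ramp))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + ramp
  }
  if (config$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), sd = config$noise_sd), dim = dim(img))
  img <- pmin(pmax(img, 0), 1)

  s <- fp_sample(img, centers, sample_id = sprintf("synthetic_%06d", config$seed))
  attr(s, "stain_ellipse") <- ell
  s
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes one PNG image and one annotation CSV per scene, plus a JSON
#' manifest recording the per-scene seeds and papilla counts.
#'
#' @param n_images Number of scenes.
#' @param config Base [scene_config()]; scene `i` uses seed `config$seed + i`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly, as a data frame.
#' @export
generate_dataset <- function(n_images, config = scene_config(), out_dir) {
  stopifnot(n_images >= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg <- config
    cfg$seed <- config$seed + i
    s <- generate_scene(cfg)
    img_file <- sprintf("scene_%04d.png", i)
    ann_file <- sprintf("scene_%04d.csv", i)
    write_image(s$image, file.path(out_dir, img_file))
    write_points(s$points, file.path(out_dir, ann_file))
    rows[[i]] <- data.frame(index = i, seed = cfg$seed, image = img_file,
                            annotations = ann_file, n_papillae = nrow(s$points))
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(list(generator = "fungiform synthetic scenes",
                            base_seed = config$seed,
                            image_size = config$image_size,
                            scenes = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate synthetic scenes in memory
#'
#' Like [generate_dataset()] but returns the [fp_sample()] objects directly
#' without touching the filesystem; scene `i` uses seed `config$seed + i`.
#'
#' @inheritParams generate_dataset
#' @return List of `fp_sample` objects.
#' @export
simulate_samples <- function(n_images, config = scene_config()) {
  lapply(seq_len(n_images), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    generate_scene(cfg)
  })
}
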