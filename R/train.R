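# Training: k-fold cross-validation with MSE loss, MAE monitoring, Adam, and
# rotation/flip/intensity augmentation. The published protocol is k = 5,
# 500 epochs, batch size 2, learning rate 1e-3; a desk-scale preset with
# reduced image size, network width and epochs is provided for small
# experiments and is always labelled as such.

#' Data augmentation settings
#'
#' @param rotation_degrees Half-range of free rotations (degrees); quarter
#'   turns are additionally sampled since papilla layout has no preferred
#'   orientation.
#' @param allow_flips Sample horizontal/vertical flips.
#' @param intensity_scale_range Multiplicative intensity range around 1,
#'   applied to the image only.
#' @param intensity_shift Half-range of the additive intensity shift.
#' @param probability Probability that a sample is augmented at all.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_degrees = 15, allow_flips = TRUE,
                                intensity_scale_range = c(0.9, 1.1),
                                intensity_shift = 0.05, probability = 0.8) {
  stopifnot(rotation_degrees >= 0, diff(intensity_scale_range) >= 0,
            probability >= 0, probability <= 1)
  structure(list(rotation_degrees = rotation_degrees,
                 allow_flips = allow_flips,
                 intensity_scale_range = intensity_scale_range,
                 intensity_shift = intensity_shift,
                 probability = probability),
            class = "augmentation_config")
}

#' Training settings
#'
#' Defaults follow the published protocol: 5 folds, 500 epochs, batch size
#' 2, MSE loss with MAE monitoring, Adam with learning rate 1e-3.
#'
#' @param k_folds Number of cross-validation folds (>= 2).
#' @param epochs Training epochs per fold.
#' @param batch_size Samples per gradient step.
#' @param learning_rate Adam learning rate.
#' @param augmentation An [augmentation_config()]; `NULL` disables
#'   augmentation.
#' @param seed Master seed; fold assignment, weight initialization and the
#'   augmentation/dropout streams all derive from it.
#' @return A `training_config` list (optimizer, loss and monitor metric are
#'   fixed to Adam / MSE / MAE).
#' @export
training_config <- function(k_folds = 5L, epochs = 500L, batch_size = 2L,
                            learning_rate = 1e-3,
                            augmentation = augmentation_config(),
                            seed = 1L) {
  stopifnot(k_folds >= 2, epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(k_folds = as.integer(k_folds), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = "Adam", loss = "MSE", monitor_metric = "MAE",
                 augmentation = augmentation, seed = as.integer(seed)),
            class = "training_config")
}

#' Random k-fold partition of sample ids
#'
#' @param sample_ids Character or integer vector of ids.
#' @param k Number of folds (`k <= length(sample_ids)`).
#' @param seed Seed controlling the shuffle.
#' @return List of `k` fold splits, each with `fold_index`, `train_ids`,
#'   `val_ids`; every id appears in exactly one validation fold and fold
#'   sizes differ by at most one.
#' @export
make_folds <- function(sample_ids, k, seed = 1L) {
  n <- length(sample_ids)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  set.seed(as.integer(seed))
  perm <- sample(sample_ids)
  # contiguous blocks over the shuffled ids, sizes differing by at most 1
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  lapply(seq_len(k), function(f) {
    val <- perm[starts[f]:ends[f]]
    list(fold_index = f, train_ids = setdiff(sample_ids, val), val_ids = val)
  })
}

# reflect an index vector into [1, n]
reflect_idx <- function(x, n) {
  if (n == 1) return(rep(1, length(x)))
  period <- 2 * (n - 1)
  x <- abs(x - 1) %% period
  ifelse(x >= n - 1, period - x, x) + 1
}

# rotate an (H,W,C) array about its center by `theta` radians (bilinear);
# pad = "reflect" mirrors the image at its borders, "zero" fills with 0
rotate_array <- function(img, theta, pad = c("reflect", "zero")) {
  pad <- match.arg(pad)
  d <- dim(img)
  cr <- (d[1] - 1) / 2; cc <- (d[2] - 1) / 2
  dst_r <- rep(seq_len(d[1]) - 1, times = d[2]) - cr
  dst_c <- rep(seq_len(d[2]) - 1, each = d[1]) - cc
  src_r <- cos(theta) * dst_r - sin(theta) * dst_c + cr
  src_c <- sin(theta) * dst_r + cos(theta) * dst_c + cc
  if (pad == "reflect") {
    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0; fc <- src_c - c0
    out <- matrix(0, length(src_r), d[3])
    for (ch in seq_len(d[3])) {
      m <- img[, , ch]
      i00 <- cbind(reflect_idx(r0 + 1, d[1]), reflect_idx(c0 + 1, d[2]))
      i10 <- cbind(reflect_idx(r0 + 2, d[1]), reflect_idx(c0 + 1, d[2]))
      i01 <- cbind(reflect_idx(r0 + 1, d[1]), reflect_idx(c0 + 2, d[2]))
      i11 <- cbind(reflect_idx(r0 + 2, d[1]), reflect_idx(c0 + 2, d[2]))
      out[, ch] <- m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
                   m[i01] * (1 - fr) * fc + m[i11] * fr * fc
    }
  } else {
    inb <- src_r >= 0 & src_r <= d[1] - 1 & src_c >= 0 & src_c <= d[2] - 1
    out <- matrix(0, length(src_r), d[3])
    if (any(inb)) out[inb, ] <- bilinear_sample(img, src_r[inb], src_c[inb])
  }
  array(out, dim = d)
}

# map point coordinates through the same rotation (for alignment checks)
rotate_points <- function(points, theta, shape) {
  p <- as_point_set(points)
  if (!nrow(p)) return(p)
  cr <- (shape[1] - 1) / 2; cc <- (shape[2] - 1) / 2
  dr <- p[, 1] - cr; dc <- p[, 2] - cc
  as_point_set(cbind(cos(theta) * dr + sin(theta) * dc + cr,
                     -sin(theta) * dr + cos(theta) * dc + cc))
}

#' Jointly augment an image / heatmap pair
#'
#' Geometric operations (flips, quarter turns, a free rotation) are applied
#' identically to image and heatmap so peak positions stay aligned; the
#' intensity adjustment touches the image only. Both outputs are clamped to
#' `[0,1]`. Draws come from the current RNG stream, so results are
#' reproducible under `set.seed`.
#'
#' @param image `(H,W,C)` image array.
#' @param heatmap `H x W` target matrix.
#' @param config An [augmentation_config()].
#' @return List `image`, `heatmap`, and `ops` (the sampled operations).
#' @export
augment_sample <- function(image, heatmap, config = augmentation_config()) {
  stopifnot(all(dim(image)[1:2] == dim(heatmap)))
  if (config$probability <= 0 || stats::runif(1) > config$probability)
    return(list(image = image, heatmap = heatmap, ops = list()))
  hm <- array(heatmap, dim = c(dim(heatmap), 1L))
  ops <- list()
  if (config$allow_flips && stats::runif(1) < 0.5) {
    image <- image[dim(image)[1]:1, , , drop = FALSE]
    hm <- hm[dim(hm)[1]:1, , , drop = FALSE]
    ops$vflip <- TRUE
  }
  if (config$allow_flips && stats::runif(1) < 0.5) {
    image <- image[, dim(image)[2]:1, , drop = FALSE]
    hm <- hm[, dim(hm)[2]:1, , drop = FALSE]
    ops$hflip <- TRUE
  }
  k90 <- sample(0:3, 1)
  if (k90 > 0 && dim(image)[1] == dim(image)[2]) {
    rot90 <- function(a, k) {
      for (q in seq_len(k)) {
        a <- aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
      }
      a
    }
    image <- rot90(image, k90)
    hm <- rot90(hm, k90)
    ops$quarter_turns <- k90
  }
  if (config$rotation_degrees > 0) {
    theta <- stats::runif(1, -1, 1) * config$rotation_degrees * pi / 180
    image <- rotate_array(image, theta, pad = "reflect")
    hm <- rotate_array(hm, theta, pad = "zero")
    ops$rotation_rad <- theta
  }
  sc <- stats::runif(1, config$intensity_scale_range[1], config$intensity_scale_range[2])
  sh <- stats::runif(1, -config$intensity_shift, config$intensity_shift)
  image <- image * sc + sh
  ops$intensity <- c(scale = sc, shift = sh)
  list(image = pmin(pmax(image, 0), 1),
       heatmap = pmin(pmax(hm[, , 1], 0), 1), ops = ops)
}

# pad an (image, heatmap) pair so spatial dims are divisible by 16
pad_pair <- function(image, heatmap) {
  p <- pad_to_multiple(image, 16L)
  hm <- heatmap
  if (p$ph > 0 || p$pw > 0) {
    hm <- matrix(0, nrow(heatmap) + p$ph, ncol(heatmap) + p$pw)
    hm[seq_len(nrow(heatmap)), seq_len(ncol(heatmap))] <- heatmap
  }
  list(image = p$img, heatmap = hm)
}

eval_pass <- function(model, pairs, batch_size) {
  # inference-mode MSE/MAE over a list of (image, heatmap) pairs
  se <- 0; ae <- 0; npx <- 0
  idx <- seq_along(pairs)
  for (b in split(idx, ceiling(idx / batch_size))) {
    pp <- lapply(pairs[b], function(s) pad_pair(s$image, s$heatmap))
    x <- stack_batch(lapply(pp, `[[`, "image"))
    gt <- stack_batch(lapply(pp, function(s) array(s$heatmap, dim = c(dim(s$heatmap), 1L))))
    out <- net_forward(model$nodes, model$out, x, training = FALSE)$out
    se <- se + sum((out - gt)^2); ae <- ae + sum(abs(out - gt)); npx <- npx + length(gt)
  }
  c(mse = se / npx, mae = ae / npx)
}

#' Train one network on (image, heatmap) pairs
#'
#' Minimizes pixelwise MSE with Adam, recording MSE and MAE on the training
#' batches (and a validation set, if given) after every epoch. No early
#' stopping: the final-epoch weights are returned.
#'
#' @param spec A `unet_spec`, or an already-instantiated `fp_model` whose
#'   weights are used as the starting point.
#' @param train_set List of samples, each a list with `image` (`(H,W,C)`
#'   array) and `heatmap` (`H x W` matrix). [fp_sample()] objects are
#'   accepted and converted using `config` and `heatmap_cfg`.
#' @param val_set Optional list of samples for per-epoch validation metrics.
#' @param config A [training_config()].
#' @param heatmap_cfg [heatmap_config()] used when `train_set` contains
#'   `fp_sample` objects.
#' @param verbose Print a progress line every 10 epochs.
#' @return The trained `fp_model`, with the per-epoch history in
#'   `$history` (data frame: epoch, train_mse, train_mae, val_mse, val_mae).
#' @export
train_model <- function(spec, train_set, val_set = NULL,
                        config = training_config(),
                        heatmap_cfg = heatmap_config(), verbose = FALSE) {
  as_pair <- function(s) {
    if (inherits(s, "fp_sample")) {
      list(image = s$image,
           heatmap = points_to_heatmap(s$points, dim(s$image)[1:2], heatmap_cfg))
    } else s
  }
  train_set <- lapply(train_set, as_pair)
  if (!is.null(val_set)) val_set <- lapply(val_set, as_pair)
  stopifnot(length(train_set) >= 1)

  model <- if (inherits(spec, "fp_model")) spec else
    instantiate(spec, seed = config$seed + 7919L)
  nodes <- model$nodes
  adam <- adam_new(nodes)
  set.seed(config$seed + 104729L)  # shuffling / augmentation / dropout stream

  hist <- data.frame(epoch = seq_len(config$epochs), train_mse = NA_real_,
                     train_mae = NA_real_, val_mse = NA_real_, val_mae = NA_real_)
  n <- length(train_set)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    se <- 0; ae <- 0; npx <- 0
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      batch <- lapply(train_set[b], function(s) {
        if (!is.null(config$augmentation)) {
          a <- augment_sample(s$image, s$heatmap, config$augmentation)
          s <- list(image = a$image, heatmap = a$heatmap)
        }
        pad_pair(s$image, s$heatmap)
      })
      x <- stack_batch(lapply(batch, `[[`, "image"))
      gt <- stack_batch(lapply(batch, function(s)
        array(s$heatmap, dim = c(dim(s$heatmap), 1L))))
      fw <- net_forward(nodes, model$out, x, training = TRUE)
      diff <- fw$out - gt
      loss <- mean(diff * diff)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep, "; reduce the learning rate")
      se <- se + sum(diff * diff); ae <- ae + sum(abs(diff)); npx <- npx + length(gt)
      grads <- net_backward(nodes, model$out, fw, 2 * diff / length(gt))
      nodes <- bn_update_running(nodes, fw$extras)
      st <- adam_step(nodes, grads, adam, lr = config$learning_rate)
      nodes <- st$nodes; adam <- st$adam
    }
    hist$train_mse[ep] <- se / npx
    hist$train_mae[ep] <- ae / npx
    if (!is.null(val_set)) {
      model$nodes <- nodes
      vm <- eval_pass(model, val_set, config$batch_size)
      hist$val_mse[ep] <- vm["mse"]; hist$val_mae[ep] <- vm["mae"]
    }
    if (verbose && (ep %% 10 == 0 || ep == 1))
      message(sprintf("epoch %d/%d: train MSE %.5f MAE %.5f%s", ep, config$epochs,
                      hist$train_mse[ep], hist$train_mae[ep],
                      if (!is.null(val_set))
                        sprintf(" | val MSE %.5f", hist$val_mse[ep]) else ""))
  }
  model$nodes <- nodes
  model$history <- hist
  model$trained <- TRUE
  model$training_config <- config
  model
}

#' Fit a papilla-detection model to annotated samples
#'
#' The package's main fitting interface: converts annotated samples to
#' Gaussian ground-truth heatmaps and trains the network. Returns a
#' fitted model with `print`, `plot` (training history) and
#' [predict.fp_model()] methods.
#'
#' @param spec A `unet_spec` (see [optimized_unet_spec()]).
#' @param samples List of [fp_sample()] objects.
#' @param config A [training_config()].
#' @param heatmap_cfg A [heatmap_config()].
#' @param val_samples Optional held-out samples for per-epoch validation.
#' @param verbose Print progress.
#' @return A trained `fp_model`.
#' @export
fit_papillae <- function(spec, samples, config = training_config(),
                         heatmap_cfg = heatmap_config(), val_samples = NULL,
                         verbose = FALSE) {
  train_model(spec, samples, val_samples, config, heatmap_cfg, verbose)
}

#' Plot training history
#'
#' MSE and MAE per epoch on a log scale, training and (when recorded)
#' validation.
#'
#' @param x A trained `fp_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fp_model <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  has_val <- !all(is.na(h$val_mse))
  for (m in c("mse", "mae")) {
    cols <- paste0(c("train_", "val_"), m)
    y <- as.matrix(h[, if (has_val) cols else cols[1], drop = FALSE])
    graphics::matplot(h$epoch, y, type = "l", log = "y", lty = 1,
                      col = c("steelblue", "darkorange"),
                      xlab = "epoch", ylab = toupper(m), ...)
    graphics::legend("topright", bty = "n", lty = 1,
                     col = c("steelblue", "darkorange"),
                     legend = c("training", "validation")[seq_len(ncol(y))])
  }
  invisible(x)
}

#' @export
summary.fp_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  best train MSE %.5g (epoch %d)\n",
                min(h$train_mse), which.min(h$train_mse)))
    if (!all(is.na(h$val_mse)))
      cat(sprintf("  best val MSE %.5g (epoch %d)\n",
                  min(h$val_mse), which.min(h$val_mse)))
  }
  invisible(object)
}

#' K-fold cross-validated training
#'
#' Splits the dataset with [make_folds()], trains one model per fold and
#' keeps each fold's history and split, mirroring the published five-fold
#' protocol.
#'
#' @param spec A `unet_spec`.
#' @param samples List of [fp_sample()] objects (or image/heatmap pairs).
#' @param config A [training_config()] (`k_folds` taken from here).
#' @param heatmap_cfg A [heatmap_config()].
#' @param verbose Print per-fold progress.
#' @return List with one element per fold: `model`, `history`, `split`.
#' @export
run_cross_validation <- function(spec, samples, config = training_config(),
                                 heatmap_cfg = heatmap_config(),
                                 verbose = FALSE) {
  n <- length(samples)
  if (n < config$k_folds) stop("dataset smaller than the number of folds")
  folds <- make_folds(seq_len(n), config$k_folds, seed = config$seed)
  lapply(folds, function(f) {
    cfg <- config
    cfg$seed <- config$seed + f$fold_index
    mdl <- tryCatch(
      train_model(spec, samples[f$train_ids], samples[f$val_ids], cfg,
                  heatmap_cfg, verbose = verbose),
      error = function(e) stop("fold ", f$fold_index, ": ", conditionMessage(e),
                               call. = FALSE))
    list(model = mdl, history = mdl$history, split = f)
  })
}

#' Desk-scale experiment preset
#'
#' A deliberately scaled-down profile for laptop-class experiments and the
#' package's own test suite: 128x128 synthetic scenes, a width-reduced
#' optimized U-Net and 50 epochs. It is a surrogate for the full protocol
#' (250x250, full width, 500 epochs), suitable for studying pipeline
#' behavior, not for reproducing full-scale accuracy.
#'
#' @param seed Master seed.
#' @return List with `scene` ([scene_config()]), `spec` (`unet_spec`),
#'   `training` ([training_config()]) and `heatmap` ([heatmap_config()]).
#' @export
desk_preset <- function(seed = 1L) {
  list(
    scene = scene_config(image_size = c(128L, 128L),
                         spot_radius_px = c(2.5, 4.5),
                         min_separation = 8,
                         background_speckle_density = 0.002,
                         seed = seed),
    spec = optimized_unet_spec(input_channels = 3L, dropout_rate = 0.2,
                               width_scale = 0.125),
    training = training_config(k_folds = 5L, epochs = 50L, batch_size = 2L,
                               learning_rate = 1e-3, seed = seed),
    heatmap = heatmap_config(sigma = 3)
  )
}
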