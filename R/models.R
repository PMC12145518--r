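# Architecture specifications and model instantiation.
#
# All three networks are encoder-decoder heatmap regressors ending in a linear
# single-channel 1x1 convolution: the output is a continuous map with high
# values at papilla centers, not a class probability.

new_unet_spec <- function(architecture, encoder_filters, middle_filters,
                          use_batch_norm, dropout_rate, middle_dropout_rate,
                          input_channels, width_scale = 1, extra = list()) {
  stopifnot(input_channels %in% c(1L, 3L), width_scale > 0,
            dropout_rate >= 0, dropout_rate < 1)
  sc <- function(f) pmax(1L, as.integer(round(f * width_scale)))
  enc <- sc(encoder_filters)
  spec <- c(list(
    architecture = architecture,
    encoder_filters = enc,
    middle_filters = sc(middle_filters),
    decoder_filters = rev(enc),
    use_batch_norm = use_batch_norm,
    dropout_rate = dropout_rate,
    middle_dropout_rate = middle_dropout_rate,
    input_channels = as.integer(input_channels),
    final_activation = "linear",
    width_scale = width_scale
  ), extra)
  class(spec) <- "unet_spec"
  spec
}

#' Classic U-Net architecture specification
#'
#' Four encoder blocks of two same-padded 3x3 convolutions each, doubling the
#' filter count from 64 to 512, a 1024-filter middle block, and a mirrored
#' decoder with 2x2 transposed-convolution upsampling and skip concatenation.
#' No batch normalization or dropout; the final layer is a linear 1x1
#' convolution producing a single-channel heatmap.
#'
#' @param input_channels 1 (grayscale) or 3 (color) input planes.
#' @param width_scale Multiplier applied to every filter count; `1` is the
#'   published architecture, fractions give reduced-width variants for
#'   small-scale experiments.
#' @return A `unet_spec` object.
#' @seealso [optimized_unet_spec()], [multires_unet_spec()], [instantiate()]
#' @export
classic_unet_spec <- function(input_channels = 3L, width_scale = 1) {
  new_unet_spec("classic_unet", c(64L, 128L, 256L, 512L), 1024L,
                use_batch_norm = FALSE, dropout_rate = 0,
                middle_dropout_rate = 0,
                input_channels = input_channels, width_scale = width_scale)
}

#' Optimized U-Net architecture specification
#'
#' A leaner U-Net variant for papilla detection: 64 filters in the first two
#' encoder blocks, 128 in the third, 256 in the fourth and 512 in the middle
#' block; batch normalization after every convolution, dropout after each
#' block (rate `dropout_rate`, 0.5 in the middle block), and the same linear
#' single-channel head as the other architectures.
#'
#' @inheritParams classic_unet_spec
#' @param dropout_rate Dropout fraction in encoder/decoder blocks, in `[0,1)`.
#' @return A `unet_spec` object.
#' @export
optimized_unet_spec <- function(input_channels = 3L, dropout_rate = 0.2,
                                width_scale = 1) {
  new_unet_spec("optimized_unet", c(64L, 64L, 128L, 256L), 512L,
                use_batch_norm = TRUE, dropout_rate = dropout_rate,
                middle_dropout_rate = 0.5,
                input_channels = input_channels, width_scale = width_scale)
}

#' MultiResUNet architecture specification
#'
#' Replaces plain convolution blocks with MultiRes blocks (three chained 3x3
#' convolutions whose outputs are concatenated, plus a 1x1 residual
#' projection) and plain skip connections with residual paths whose length
#' shrinks with depth (4 units at the shallowest stage, 1 at the deepest).
#' Filter budgets derive from a base width of 32 scaled by `alpha`.
#'
#' @inheritParams classic_unet_spec
#' @param alpha Filter budget scale factor for MultiRes blocks (default 1.67).
#' @return A `unet_spec` object.
#' @export
multires_unet_spec <- function(input_channels = 3L, width_scale = 1,
                               alpha = 1.67) {
  new_unet_spec("multires_unet", c(32L, 64L, 128L, 256L), 512L,
                use_batch_norm = TRUE, dropout_rate = 0,
                middle_dropout_rate = 0,
                input_channels = input_channels, width_scale = width_scale,
                extra = list(base_filters = max(1L, as.integer(round(32 * width_scale))),
                             alpha = alpha))
}

#' @export
print.unet_spec <- function(x, ...) {
  cat("<unet_spec>", x$architecture, "\n")
  cat("  encoder filters:", paste(x$encoder_filters, collapse = ", "),
      "| middle:", x$middle_filters, "\n")
  cat("  batch norm:", x$use_batch_norm,
      "| dropout:", x$dropout_rate,
      "| input channels:", x$input_channels,
      "| final activation:", x$final_activation, "\n")
  cat("  trainable parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Count trainable parameters of an architecture
#'
#' Sums kernel weights, biases and batch-normalization scale/shift parameters
#' over the compiled layer graph (running statistics are not trainable and are
#' excluded).
#'
#' @param spec A `unet_spec`.
#' @return Integer-valued parameter count.
#' @export
count_parameters <- function(spec) {
  net <- compile_spec(spec)
  tot <- 0
  for (nd in net$nodes) {
    if (!is.null(nd$pshape)) tot <- tot + sum(vapply(nd$pshape, prod, 1))
  }
  tot
}

#' Instantiate a network from its specification
#'
#' Allocates and initializes all weights (He-normal for convolutions, unit
#' scale / zero shift for batch normalization) deterministically under the
#' given seed, returning a trainable model object.
#'
#' @param spec A `unet_spec`.
#' @param seed Integer seed controlling weight initialization.
#' @return An object of class `fp_model` supporting [predict.fp_model()],
#'   `print`, and [fit_papillae()] for training.
#' @export
instantiate <- function(spec, seed = 1L) {
  net <- compile_spec(spec)
  nodes <- init_params(net$nodes, seed)
  structure(list(spec = spec, nodes = nodes, out = net$out,
                 history = NULL, trained = FALSE, seed = seed),
            class = "fp_model")
}

#' @export
print.fp_model <- function(x, ...) {
  cat("<fp_model>", x$spec$architecture,
      if (isTRUE(x$trained)) "(trained)" else "(untrained)", "\n")
  cat("  parameters:", format(count_parameters(x$spec), big.mark = ","), "\n")
  if (!is.null(x$history)) {
    n <- nrow(x$history)
    cat(sprintf("  %d epochs; final train MSE %.4g, MAE %.4g\n",
                n, x$history$train_mse[n], x$history$train_mae[n]))
  }
  invisible(x)
}

# reflection-pad an (H,W,C) image so both spatial dims are multiples of `m`
pad_to_multiple <- function(img, m = 16L) {
  d <- dim(img)
  ph <- (m - d[1] %% m) %% m
  pw <- (m - d[2] %% m) %% m
  if (ph == 0 && pw == 0) return(list(img = img, ph = 0L, pw = 0L))
  ri <- c(seq_len(d[1]), rev(seq_len(d[1]))[seq_len(ph)])
  ci <- c(seq_len(d[2]), rev(seq_len(d[2]))[seq_len(pw)])
  list(img = img[ri, ci, , drop = FALSE], ph = ph, pw = pw)
}

# stack a list of (H,W,C) arrays into (H,W,C,N)
stack_batch <- function(imgs) {
  d <- dim(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), dim = c(d, length(imgs)))
}

#' Predict heatmaps from images
#'
#' Runs the network in inference mode (dropout disabled, batch-normalization
#' running statistics). Inputs whose spatial size is not divisible by 16 are
#' reflection-padded internally and the output is cropped back, so the
#' returned heatmap always matches the input's spatial shape.
#'
#' @param object A trained or untrained `fp_model`.
#' @param newdata A single `(H,W,C)` image array or a list of them. Channel
#'   count must match the spec.
#' @param clamp Clamp the linear-head output into `[0,1]` (default `TRUE`).
#' @param ... Unused.
#' @return A single `H x W` heatmap matrix, or a list of them.
#' @export
predict.fp_model <- function(object, newdata, clamp = TRUE, ...) {
  single <- is.array(newdata) || is.matrix(newdata)
  imgs <- if (single) list(newdata) else newdata
  out <- lapply(imgs, function(img) {
    img <- as_image_array(img)
    if (dim(img)[3] != object$spec$input_channels) {
      stop("input has ", dim(img)[3], " channels but the spec expects ",
           object$spec$input_channels)
    }
    d0 <- dim(img)
    p <- pad_to_multiple(img, 16L)
    x <- array(p$img, dim = c(dim(p$img), 1L))
    y <- net_forward(object$nodes, object$out, x, training = FALSE)$out
    h <- y[seq_len(d0[1]), seq_len(d0[2]), 1L, 1L]
    if (clamp) h <- pmin(pmax(h, 0), 1)
    h
  })
  if (single) out[[1]] else out
}
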