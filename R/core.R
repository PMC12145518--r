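# Core data types and readers/writers.
#
# Conventions fixed project-wide:
#   * images are numeric arrays dim (H, W, C), C in {1,3}, intensities in [0,1]
#   * point coordinates are (row, col), 0-based, pixel centers at integers
#   * heatmaps are H x W matrices in [0,1]

#' Coerce to a validated image array
#'
#' Accepts an `H x W` matrix (promoted to one channel) or an `(H,W,C)` array
#' with 1 or 3 channels, and checks that all intensities are finite and in
#' `[0,1]`.
#'
#' @param x Matrix or 3-d array.
#' @return A numeric `(H,W,C)` array.
#' @export
as_image_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L || !dim(x)[3] %in% c(1L, 3L))
    stop("image must be an (H, W, C) array with 1 or 3 channels")
  if (!all(is.finite(x))) stop("image contains non-finite values")
  if (min(x) < 0 || max(x) > 1) stop("image intensities must lie in [0,1]")
  x
}

#' Coerce to a point set matrix
#'
#' @param p `NULL` (empty set), a length-2 vector, or an `n x 2` matrix /
#'   data frame of `(row, col)` coordinates.
#' @return An `n x 2` numeric matrix with columns `row`, `col`.
#' @export
as_point_set <- function(p) {
  if (is.null(p) || (is.matrix(p) && nrow(p) == 0) || length(p) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  if (is.data.frame(p)) p <- as.matrix(p[, c("row", "col")])
  if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = TRUE)
  storage.mode(p) <- "double"
  if (ncol(p) != 2) stop("points must have two columns (row, col)")
  if (!all(is.finite(p))) stop("points contain non-finite coordinates")
  colnames(p) <- c("row", "col")
  p
}

#' Read an image file
#'
#' Supports PNG, JPEG and TIFF (8- or 16-bit); intensities are rescaled to
#' `[0,1]` and the channel count is preserved (grayscale stays 1 channel,
#' color becomes 3; an alpha channel, if present, is discarded).
#'
#' @param path Path to the image file.
#' @return An `(H,W,C)` image array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (PNG/JPEG/TIFF supported): ", path))
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (dim(x)[3] == 2L) x <- x[, , 1L, drop = FALSE]          # gray + alpha
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]         # rgba -> rgb
  as_image_array(pmin(pmax(x, 0), 1))
}

#' Write an image file
#'
#' PNG/JPEG for display images; TIFF is written as 32-bit float and is the
#' format used to persist continuous heatmaps losslessly.
#'
#' @param img Image array or heatmap matrix (values in `[0,1]`).
#' @param path Destination; format chosen from the extension.
#' @export
write_image <- function(img, path) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  ext <- tolower(tools::file_ext(path))
  x <- if (dim(img)[3] == 1L) img[, , 1L] else img
  switch(ext,
    png = png::writePNG(x, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(x, path, quality = 0.95),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 32L),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Read point annotations
#'
#' CSV files must have a `row,col` header; JSON files hold a list of
#' `[row, col]` pairs. Point order is preserved.
#'
#' @param path Path to a `.csv` or `.json` annotation file.
#' @return An `n x 2` point matrix.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (length(raw) == 0) return(as_point_set(NULL))
    p <- matrix(as.numeric(t(raw)), ncol = 2, byrow = TRUE)
  } else if (ext == "csv") {
    df <- tryCatch(utils::read.csv(path), error = function(e)
      stop("malformed annotation CSV ", path, ": ", conditionMessage(e)))
    if (!all(c("row", "col") %in% names(df)))
      stop("annotation CSV must have a 'row,col' header: ", path)
    bad <- which(!stats::complete.cases(df[, c("row", "col")]) |
                 !vapply(seq_len(nrow(df)), function(i)
                   is.numeric(df$row[i]) && is.numeric(df$col[i]), TRUE))
    if (length(bad))
      stop("malformed annotation row at line ", bad[1] + 1L, " of ", path)
    p <- as.matrix(df[, c("row", "col")])
  } else stop("unsupported annotation format: ", ext)
  if (length(p) && min(p) < 0) stop("negative coordinate in ", path)
  as_point_set(p)
}

#' Write point annotations
#'
#' @param points Point matrix (see [as_point_set()]).
#' @param path Destination `.csv` (with `row,col` header) or `.json`.
#' @export
write_points <- function(points, path) {
  points <- as_point_set(points)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unname(apply(points, 1, function(r) r, simplify = FALSE)),
                         path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(as.data.frame(points), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# ---- geometric transforms ----------------------------------------------------

#' Create a geometric transform (crop offset + scale)
#'
#' Maps points by `(p - crop_offset) * scale` when `order = "crop_then_scale"`
#' or `p * scale - crop_offset` when `order = "scale_then_crop"` (the latter
#' arises as the inverse of the former). Used to keep point annotations
#' aligned with image cropping and resizing.
#'
#' @param crop_offset Length-2 `(row, col)` offset in pixels.
#' @param scale Length-2 positive `(row, col)` scale factors.
#' @param order `"crop_then_scale"` or `"scale_then_crop"`.
#' @return An `fp_transform` object.
#' @export
fp_transform <- function(crop_offset = c(0, 0), scale = c(1, 1),
                         order = c("crop_then_scale", "scale_then_crop")) {
  order <- match.arg(order)
  stopifnot(length(crop_offset) == 2, length(scale) == 2, all(scale > 0))
  structure(list(crop_offset = as.numeric(crop_offset),
                 scale = as.numeric(scale), order = order),
            class = "fp_transform")
}

#' Invert a geometric transform
#' @param t An `fp_transform`.
#' @return The inverse `fp_transform`.
#' @export
inverse_transform <- function(t) {
  # (p - off) * s  inverts to  p' / s + off;  p * s - off  to  (p' + off) / s
  fp_transform(crop_offset = -t$crop_offset, scale = 1 / t$scale,
               order = if (t$order == "crop_then_scale") "scale_then_crop"
                       else "crop_then_scale")
}

#' Apply a geometric transform to points
#'
#' Points that land outside `bounds` (if given) are dropped; the number
#' dropped is recorded in the `"n_dropped"` attribute rather than raising an
#' error, since cropping legitimately discards annotations outside the
#' stained region.
#'
#' @param points Point matrix.
#' @param t An `fp_transform`.
#' @param bounds Optional `(rows, cols)` of the target grid; points outside
#'   `[-0.5, rows-0.5) x [-0.5, cols-0.5)` are dropped.
#' @return Transformed point matrix with attribute `n_dropped`.
#' @export
transform_points <- function(points, t, bounds = NULL) {
  p <- as_point_set(points)
  if (nrow(p)) {
    if (t$order == "crop_then_scale") {
      p <- sweep(sweep(p, 2, t$crop_offset, "-"), 2, t$scale, "*")
    } else {
      p <- sweep(sweep(p, 2, t$scale, "*"), 2, t$crop_offset, "-")
    }
  }
  n_dropped <- 0L
  if (!is.null(bounds) && nrow(p)) {
    keep <- p[, 1] >= -0.5 & p[, 1] < bounds[1] - 0.5 &
            p[, 2] >= -0.5 & p[, 2] < bounds[2] - 0.5
    n_dropped <- sum(!keep)
    p <- p[keep, , drop = FALSE]
  }
  attr(p, "n_dropped") <- n_dropped
  p
}

# ---- annotated samples -------------------------------------------------------

#' Bundle an image with its papilla annotations
#'
#' @param image `(H,W,C)` image array.
#' @param points Point matrix of papilla centers (row, col).
#' @param sample_id Identifier string.
#' @param transforms List of `fp_transform`s already applied (provenance).
#' @return An `fp_sample` object.
#' @export
fp_sample <- function(image, points = NULL, sample_id = "sample",
                      transforms = list()) {
  image <- as_image_array(image)
  points <- as_point_set(points)
  if (nrow(points)) {
    d <- dim(image)
    if (min(points) < -0.5 || max(points[, 1]) >= d[1] - 0.5 ||
        max(points[, 2]) >= d[2] - 0.5)
      stop("annotations fall outside the image bounds")
  }
  structure(list(image = image, points = points, sample_id = sample_id,
                 transforms = transforms, n_dropped = 0L),
            class = "fp_sample")
}

#' @export
print.fp_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<fp_sample> '%s': %dx%d image (%d channel%s), %d annotated papilla(e)\n",
              x$sample_id, d[1], d[2], d[3], if (d[3] > 1) "s" else "",
              nrow(x$points)))
  if (x$n_dropped > 0) cat("  ", x$n_dropped, "annotation(s) dropped by cropping\n")
  invisible(x)
}
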