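# Ground-truth heatmap construction and local-peak detection (LPD).
#
# Each annotated papilla center contributes a unit-peak isotropic Gaussian
# exp(-d^2 / (2 sigma^2)); overlapping kernels are combined with a pixelwise
# maximum by default so targets stay in [0,1]. Peak extraction is the inverse
# step: local maxima over a square neighborhood, thresholded relative to the
# map maximum with an absolute floor against near-empty predictions.

#' Heatmap construction and peak-detection settings
#'
#' @param sigma Gaussian kernel width in pixels (default 3, matched to the
#'   apparent papilla radius at the standard 250x250 resolution).
#' @param combine_mode `"max"` (default) keeps overlapping targets bounded at
#'   1; `"sum"` gives an additive density map, clamped to `[0,1]`.
#' @param peak_min_distance Neighborhood half-width for local maxima; two
#'   reported peaks are always more than this many pixels apart.
#' @param peak_threshold_rel Fraction of the map maximum below which local
#'   maxima are discarded, in (0,1).
#' @param peak_threshold_abs Absolute floor on peak values, suppressing noise
#'   peaks on near-empty maps.
#' @return A `heatmap_config` list.
#' @export
heatmap_config <- function(sigma = 3, combine_mode = c("max", "sum"),
                           peak_min_distance = 3L, peak_threshold_rel = 0.2,
                           peak_threshold_abs = 0.05) {
  combine_mode <- match.arg(combine_mode)
  stopifnot(sigma > 0, peak_min_distance >= 1,
            peak_threshold_rel > 0, peak_threshold_rel < 1,
            peak_threshold_abs >= 0)
  structure(list(sigma = sigma, combine_mode = combine_mode,
                 peak_min_distance = as.integer(peak_min_distance),
                 peak_threshold_rel = peak_threshold_rel,
                 peak_threshold_abs = peak_threshold_abs),
            class = "heatmap_config")
}

#' Convert point annotations to a Gaussian heatmap
#'
#' @param points Point matrix of papilla centers, `(row, col)` 0-based.
#' @param shape `(rows, cols)` of the output grid.
#' @param config A [heatmap_config()].
#' @return An `rows x cols` matrix in `[0,1]`; all zeros for an empty set.
#' @export
points_to_heatmap <- function(points, shape, config = heatmap_config()) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 1)) stop("shape must be positive (rows, cols)")
  points <- as_point_set(points)
  hm <- matrix(0, shape[1], shape[2])
  if (!nrow(points)) return(hm)
  if (min(points) < -0.5 || max(points[, 1]) >= shape[1] - 0.5 ||
      max(points[, 2]) >= shape[2] - 0.5)
    stop("points fall outside the heatmap shape")
  halfw <- ceiling(4 * config$sigma)
  for (k in seq_len(nrow(points))) {
    r <- points[k, 1]; c <- points[k, 2]
    ri <- max(0, floor(r - halfw)):min(shape[1] - 1, ceiling(r + halfw))
    ci <- max(0, floor(c - halfw)):min(shape[2] - 1, ceiling(c + halfw))
    g <- exp(-outer((ri - r)^2, (ci - c)^2, "+") / (2 * config$sigma^2))
    blk <- hm[ri + 1L, ci + 1L, drop = FALSE]
    hm[ri + 1L, ci + 1L] <- if (config$combine_mode == "max") pmax(blk, g) else blk + g
  }
  if (config$combine_mode == "sum") hm <- pmin(hm, 1)
  hm
}

#' Detect local peaks in a continuous map
#'
#' A pixel is a peak candidate if no pixel in its `(2 d + 1)`-square
#' neighborhood (`d = peak_min_distance`) has a larger value, and its value
#' reaches both the relative threshold (`peak_threshold_rel` times the map
#' maximum) and the absolute floor. Candidates are then greedily accepted in
#' order of decreasing value (ties broken by smaller row, then smaller
#' column), suppressing further candidates within `d` pixels (Chebyshev), so
#' plateaus yield a single deterministic peak.
#'
#' @param map Numeric matrix (finite values).
#' @param config A [heatmap_config()].
#' @return Point matrix of peak positions at integer `(row, col)`, 0-based.
#' @export
detect_peaks <- function(map, config = heatmap_config()) {
  if (!is.matrix(map) || !all(is.finite(map))) stop("map must be a finite matrix")
  d <- config$peak_min_distance
  mx <- max(map)
  thr <- max(config$peak_threshold_rel * mx, config$peak_threshold_abs)
  if (mx <= 0 || mx < thr) return(as_point_set(NULL))
  nr <- nrow(map); nc <- ncol(map)
  # dilation by a (2d+1) square via shifted pmax
  dil <- map
  pad <- matrix(-Inf, nr + 2 * d, nc + 2 * d)
  pad[d + seq_len(nr), d + seq_len(nc)] <- map
  for (dj in -d:d) for (di in -d:d) {
    if (di == 0 && dj == 0) next
    dil <- pmax(dil, pad[d + seq_len(nr) + di, d + seq_len(nc) + dj])
  }
  cand <- which(map >= dil & map >= thr, arr.ind = TRUE)
  if (!nrow(cand)) return(as_point_set(NULL))
  v <- map[cand]
  ord <- order(-v, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  taken_r <- integer(0); taken_c <- integer(0)
  for (k in seq_len(nrow(cand))) {
    if (length(taken_r) &&
        any(abs(taken_r - cand[k, 1]) <= d & abs(taken_c - cand[k, 2]) <= d)) next
    keep[k] <- TRUE
    taken_r <- c(taken_r, cand[k, 1]); taken_c <- c(taken_c, cand[k, 2])
  }
  pts <- cand[keep, , drop = FALSE] - 1L  # back to 0-based
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  as_point_set(pts)
}
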