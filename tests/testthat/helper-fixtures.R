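# Shared fixtures: tiny deterministic scenes and random point sets.

tiny_scene <- function(seed = 1L, n_spots = 10L, size = 128L) {
  generate_scene(scene_config(image_size = c(size, size), n_spots = n_spots,
                              spot_radius_px = c(2.5, 4.5), min_separation = 8,
                              seed = seed))
}

# random integer point set with pairwise separation and border margin
random_point_set <- function(n, shape, min_sep, margin) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < 20000) {
    tries <- tries + 1
    p <- c(sample(margin:(shape[1] - 1 - margin), 1),
           sample(margin:(shape[2] - 1 - margin), 1))
    if (!nrow(pts) || min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) > min_sep)
      pts <- rbind(pts, p)
  }
  as_point_set(pts)
}

sort_points <- function(p) {
  p <- as_point_set(p)
  attr(p, "n_dropped") <- NULL
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

# brute-force local-maximum scan: the independent oracle for detect_peaks
brute_force_peaks <- function(map, d, thr_rel, thr_abs) {
  mx <- max(map)
  thr <- max(thr_rel * mx, thr_abs)
  if (mx <= 0 || mx < thr) return(as_point_set(NULL))
  nr <- nrow(map); nc <- ncol(map)
  cand <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- map[i, j]
    if (v < thr) next
    ri <- max(1, i - d):min(nr, i + d)
    ci <- max(1, j - d):min(nc, j + d)
    if (v >= max(map[ri, ci])) cand[[length(cand) + 1]] <- c(i, j, v)
  }
  if (!length(cand)) return(as_point_set(NULL))
  cand <- do.call(rbind, cand)
  ord <- order(-cand[, 3], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)
  for (k in seq_len(nrow(cand))) {
    if (!nrow(keep) ||
        !any(abs(keep[, 1] - cand[k, 1]) <= d & abs(keep[, 2] - cand[k, 2]) <= d))
      keep <- rbind(keep, cand[k, 1:2])
  }
  sort_points(keep - 1)
}

# exhaustive one-to-one assignment oracle for match_points (small sets):
# maximizes matched pairs within radius, then minimizes total distance
brute_force_match <- function(gt, pred, radius) {
  gt <- as_point_set(gt); pred <- as_point_set(pred)
  ngt <- nrow(gt); npred <- nrow(pred)
  if (ngt == 0 || npred == 0) return(list(tp = 0L, dist = 0))
  dmat <- sqrt(outer(gt[, 1], pred[, 1], "-")^2 + outer(gt[, 2], pred[, 2], "-")^2)
  best <- list(tp = 0L, dist = Inf)
  rec <- function(i, used, tp, dist) {
    # prune: even matching everything remaining cannot beat best
    if (tp + (ngt - i + 1) < best$tp) return()
    if (i > ngt) {
      if (tp > best$tp || (tp == best$tp && dist < best$dist))
        best <<- list(tp = tp, dist = dist)
      return()
    }
    rec(i + 1, used, tp, dist)  # leave gt i unmatched
    for (j in seq_len(npred)) {
      if (!used[j] && dmat[i, j] <= radius) {
        used[j] <- TRUE
        rec(i + 1, used, tp + 1L, dist + dmat[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(npred), 0L, 0)
  if (!is.finite(best$dist)) best$dist <- 0
  best$dist <- unname(best$dist)
  best
}
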