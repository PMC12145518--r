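# Evaluation: image-level metrics (MAE, SSIM, Dice), local-peak matching of
# predicted vs annotated papilla centers into TP/UP/UN, the derived detection
# rates, and per-fold mean +/- SD aggregation.
#
# Terminology follows taste-research usage: an Untrue Positive (UP) is a
# predicted papilla that does not exist, an Untrue Negative (UN) is an
# existing papilla the model missed.

#' Mean absolute error between two heatmaps
#' @param pred,gt Equal-shaped numeric matrices.
#' @return Mean over pixels of `|pred - gt|`.
#' @export
mae_metric <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("heatmap shapes differ")
  mean(abs(pred - gt))
}

# separable Gaussian filtering with symmetric (edge-reflecting) padding
gaussian_filter2 <- function(m, sigma = 1.5, width = 11L) {
  h <- (width - 1L) %/% 2L
  kern <- exp(-((-h:h)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(h)), seq_len(nr), nr + 1L - seq_len(h))
  ci <- c(rev(seq_len(h)), seq_len(nc), nc + 1L - seq_len(h))
  p <- m[ri, ci, drop = FALSE]
  tmp <- matrix(0, nr, nc + 2L * h)
  for (k in seq_len(width))
    tmp <- tmp + kern[k] * p[k:(k + nr - 1L), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_len(width))
    out <- out + kern[k] * tmp[, k:(k + nc - 1L), drop = FALSE]
  out
}

#' Structural similarity index between two heatmaps
#'
#' Windowed SSIM with the standard stabilization constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic range `L = 1`, using a
#' Gaussian window (sigma 1.5, width 11) and symmetric border handling; the
#' per-window index is averaged over all pixels.
#'
#' @param pred,gt Equal-shaped matrices with values in `[0,1]`.
#' @return SSIM value in `[-1, 1]`; 1 for identical maps.
#' @export
ssim_metric <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("heatmap shapes differ")
  C1 <- 0.01^2; C2 <- 0.03^2
  mu_x <- gaussian_filter2(pred); mu_y <- gaussian_filter2(gt)
  sxx <- gaussian_filter2(pred * pred) - mu_x^2
  syy <- gaussian_filter2(gt * gt) - mu_y^2
  sxy <- gaussian_filter2(pred * gt) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * sxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Dice overlap coefficient between binarized heatmaps
#'
#' Both maps are thresholded and the overlap `2 |A intersect B| / (|A| + |B|)`
#' of the resulting masks is returned: 0 means no overlap, 1 perfect overlap.
#' Two empty masks count as perfect agreement.
#'
#' @param pred,gt Equal-shaped matrices.
#' @param threshold Binarization threshold (default 0.5 of the unit peak
#'   amplitude).
#' @return Dice coefficient in `[0,1]`.
#' @export
dice_metric <- function(pred, gt, threshold = 0.5) {
  if (!identical(dim(pred), dim(gt))) stop("heatmap shapes differ")
  a <- pred >= threshold; b <- gt >= threshold
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# O(n^3) shortest-augmenting-path solver for the square min-cost assignment
# problem; returns for each row the assigned column.
lap_solve <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n); v <- numeric(n + 1L)
  p <- integer(n + 1L)    # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      js <- which(!used & seq_len(n + 1L) > 1L)
      if (length(js)) {
        cur <- cost[i0, js - 1L] - u[i0] - v[js]
        upd <- cur < minv[js]
        minv[js[upd]] <- cur[upd]
        way[js[upd]] <- j0
        j1 <- js[which.min(minv[js])]
        delta <- minv[j1]
      }
      iu <- which(used)
      u[p[iu]] <- u[p[iu]] + delta
      v[iu] <- v[iu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' Match predicted against ground-truth papilla centers
#'
#' Computes the optimal one-to-one assignment between ground-truth and
#' predicted points — maximizing the number of pairs within `radius`, then
#' minimizing the total matched distance — via a shortest-augmenting-path
#' assignment solver. Matched pairs are TPs, unmatched predictions UPs,
#' unmatched ground-truth points UNs.
#'
#' @param gt,pred Point matrices `(row, col)`.
#' @param radius Maximum matching distance in pixels.
#' @return A `detection_outcome` list: `tp`, `up`, `un`, `matched_pairs`
#'   (data frame of gt/pred coordinates and distances).
#' @export
match_points <- function(gt, pred, radius = 5) {
  stopifnot(radius > 0)
  gt <- as_point_set(gt); pred <- as_point_set(pred)
  ngt <- nrow(gt); npred <- nrow(pred)
  pairs <- data.frame(gt_row = numeric(0), gt_col = numeric(0),
                      pred_row = numeric(0), pred_col = numeric(0),
                      distance = numeric(0))
  tp <- 0L
  if (ngt > 0 && npred > 0) {
    BIG <- 1e9
    dmat <- sqrt(outer(gt[, 1], pred[, 1], "-")^2 +
                 outer(gt[, 2], pred[, 2], "-")^2)
    n <- max(ngt, npred)
    cost <- matrix(BIG, n, n)
    feas <- dmat <= radius
    cost[seq_len(ngt), seq_len(npred)][feas] <- dmat[feas]
    assign <- lap_solve(cost)
    for (i in seq_len(ngt)) {
      j <- assign[i]
      if (j <= npred && cost[i, j] < BIG / 2) {
        tp <- tp + 1L
        pairs <- rbind(pairs, data.frame(
          gt_row = gt[i, 1], gt_col = gt[i, 2],
          pred_row = pred[j, 1], pred_col = pred[j, 2],
          distance = dmat[i, j]))
      }
    }
  }
  structure(list(tp = tp, up = npred - tp, un = ngt - tp,
                 n_gt = ngt, n_pred = npred, radius = radius,
                 matched_pairs = pairs),
            class = "detection_outcome")
}

#' @export
print.detection_outcome <- function(x, ...) {
  cat(sprintf("<detection_outcome> TP %d | UP %d | UN %d (gt %d, predicted %d, radius %g px)\n",
              x$tp, x$up, x$un, x$n_gt, x$n_pred, x$radius))
  invisible(x)
}

#' Detection rates from a matching outcome
#'
#' The three headline percentages — TP rate `TP / GT * 100`, accurate count
#' `TP / (TP + UP) * 100` and complete accuracy `TP / (TP + UP + UN) * 100` —
#' plus UP and UN as percentages of ground truth. Rates with a zero
#' denominator are reported as `NA` (undefined), never as silent zeros.
#'
#' @param outcome A `detection_outcome` (or any list with `tp`, `up`, `un`).
#' @return A `rate_report` list of percentages.
#' @export
detection_rates <- function(outcome) {
  tp <- outcome$tp; up <- outcome$up; un <- outcome$un
  gt <- tp + un
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    tp_rate_pct = rate(tp, gt),
    un_rate_pct = rate(un, gt),
    up_rate_pct = rate(up, gt),
    accurate_count_pct = rate(tp, tp + up),
    complete_accuracy_pct = rate(tp, tp + up + un)
  ), class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  f <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat("<rate_report>\n")
  cat("  TP rate (TP/GT):            ", f(x$tp_rate_pct), "\n")
  cat("  UN rate (UN/GT):            ", f(x$un_rate_pct), "\n")
  cat("  UP rate (UP/GT):            ", f(x$up_rate_pct), "\n")
  cat("  accurate count (TP/(TP+UP)):", f(x$accurate_count_pct), "\n")
  cat("  complete accuracy:          ", f(x$complete_accuracy_pct), "\n")
  invisible(x)
}

#' Evaluate a model on a set of annotated samples
#'
#' For each sample: predict the heatmap, compare against the Gaussian
#' ground-truth heatmap (MAE, SSIM, Dice), extract predicted centers by local
#' peak detection and match them to the annotations.
#'
#' @param model An `fp_model`.
#' @param samples List of [fp_sample()] objects (a validation fold).
#' @param config [heatmap_config()] used for both ground truth and peak
#'   extraction.
#' @param radius Matching radius in pixels (reported alongside all rates).
#' @param dice_threshold Binarization threshold for the Dice coefficient.
#' @return An `fp_eval` object: `per_image` data frame, aggregate mean/SD,
#'   fold-level `rates`, and the settings used.
#' @export
evaluate_model <- function(model, samples, config = heatmap_config(),
                           radius = 5, dice_threshold = 0.5) {
  stopifnot(length(samples) >= 1)
  rows <- lapply(samples, function(s) {
    pred <- predict(model, s$image)
    gt_hm <- points_to_heatmap(s$points, dim(s$image)[1:2], config)
    peaks <- detect_peaks(pred, config)
    oc <- match_points(s$points, peaks, radius)
    data.frame(sample_id = s$sample_id,
               mae = mae_metric(pred, gt_hm),
               ssim = ssim_metric(pred, gt_hm),
               dice = dice_metric(pred, gt_hm, dice_threshold),
               gt_count = oc$n_gt, pred_count = oc$n_pred,
               tp = oc$tp, up = oc$up, un = oc$un)
  })
  per_image <- do.call(rbind, rows)
  metrics <- c("mae", "ssim", "dice", "gt_count", "pred_count", "tp", "up", "un")
  agg <- data.frame(metric = metrics,
                    mean = vapply(metrics, function(m) mean(per_image[[m]]), 1),
                    sd = vapply(metrics, function(m) stats::sd(per_image[[m]]), 1))
  rates <- detection_rates(list(tp = sum(per_image$tp), up = sum(per_image$up),
                                un = sum(per_image$un)))
  structure(list(per_image = per_image, aggregate = agg, rates = rates,
                 radius = radius, sigma = config$sigma,
                 peak_min_distance = config$peak_min_distance,
                 peak_threshold_rel = config$peak_threshold_rel,
                 dice_threshold = dice_threshold),
            class = "fp_eval")
}

#' @export
print.fp_eval <- function(x, ...) {
  cat(sprintf("<fp_eval> %d images (radius %g px, sigma %g px)\n",
              nrow(x$per_image), x$radius, x$sigma))
  a <- x$aggregate
  for (m in c("mae", "ssim", "dice")) {
    r <- a[a$metric == m, ]
    cat(sprintf("  %-5s %.4f +/- %.4f\n", toupper(m), r$mean, r$sd))
  }
  print(x$rates)
  invisible(x)
}

#' @export
summary.fp_eval <- function(object, ...) {
  print(object)
  invisible(object$aggregate)
}

#' Overlay detection outcomes on an image
#'
#' Marks matched ground-truth points (TPs) in green, spurious predictions
#' (UPs) in red and missed papillae (UNs) in blue, using small filled
#' squares, for visual inspection of a model's behavior.
#'
#' @param image `(H,W,C)` image array (grayscale is expanded to color).
#' @param gt,pred Ground-truth and predicted point sets.
#' @param radius Matching radius passed to [match_points()].
#' @param mark_halfwidth Half-width of the drawn markers in pixels.
#' @return A 3-channel image array with markers drawn.
#' @export
overlay_outcome <- function(image, gt, pred, radius = 5, mark_halfwidth = 2L) {
  image <- as_image_array(image)
  if (dim(image)[3] == 1L) image <- array(rep(image, 3), dim = c(dim(image)[1:2], 3))
  oc <- match_points(gt, pred, radius)
  draw <- function(img, pts, col) {
    d <- dim(img)
    for (k in seq_len(nrow(pts))) {
      ri <- max(1, round(pts[k, 1]) + 1 - mark_halfwidth):
            min(d[1], round(pts[k, 1]) + 1 + mark_halfwidth)
      ci <- max(1, round(pts[k, 2]) + 1 - mark_halfwidth):
            min(d[2], round(pts[k, 2]) + 1 + mark_halfwidth)
      for (ch in 1:3) img[ri, ci, ch] <- col[ch]
    }
    img
  }
  gt <- as_point_set(gt); pred <- as_point_set(pred)
  mp <- oc$matched_pairs
  tp_pts <- if (nrow(mp)) cbind(mp$gt_row, mp$gt_col) else matrix(numeric(0), 0, 2)
  is_matched_pred <- rep(FALSE, nrow(pred))
  if (nrow(mp)) {
    for (k in seq_len(nrow(mp)))
      is_matched_pred[which(pred[, 1] == mp$pred_row[k] &
                            pred[, 2] == mp$pred_col[k])[1]] <- TRUE
  }
  un_pts <- gt[!(paste(gt[, 1], gt[, 2]) %in% paste(tp_pts[, 1], tp_pts[, 2])), ,
               drop = FALSE]
  image <- draw(image, tp_pts, c(0, 0.9, 0))                       # TP green
  image <- draw(image, pred[!is_matched_pred, , drop = FALSE], c(0.9, 0, 0))  # UP red
  image <- draw(image, un_pts, c(0, 0.2, 0.95))                    # UN blue
  image
}

#' Aggregate evaluation reports across folds
#'
#' Cross-fold mean +/- SD for every metric; TP/UP/UN percentages are computed
#' per fold against that fold's total ground-truth count, then averaged
#' (fold-level normalization), matching how cross-validated detection rates
#' are conventionally reported. Also exports the per-image count table for
#' external statistical analysis.
#'
#' @param reports List of `fp_eval` objects (one per fold).
#' @return An `fp_cv_summary`: `by_fold` rate table, `summary` mean/SD table,
#'   `counts` per-image export.
#' @export
aggregate_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  fold_rows <- lapply(seq_along(reports), function(k) {
    r <- reports[[k]]
    pi <- r$per_image
    rr <- detection_rates(list(tp = sum(pi$tp), up = sum(pi$up), un = sum(pi$un)))
    data.frame(fold = k,
               mae = mean(pi$mae), ssim = mean(pi$ssim), dice = mean(pi$dice),
               gt = sum(pi$gt_count), tp = sum(pi$tp), up = sum(pi$up),
               un = sum(pi$un),
               tp_rate_pct = rr$tp_rate_pct, un_rate_pct = rr$un_rate_pct,
               up_rate_pct = rr$up_rate_pct,
               accurate_count_pct = rr$accurate_count_pct,
               complete_accuracy_pct = rr$complete_accuracy_pct)
  })
  by_fold <- do.call(rbind, fold_rows)
  num <- setdiff(names(by_fold), "fold")
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)  # single fold: SD 0
  summary_tab <- data.frame(
    metric = num,
    mean = vapply(num, function(m) mean(by_fold[[m]]), 1),
    sd = vapply(num, function(m) sd0(by_fold[[m]]), 1))
  counts <- do.call(rbind, lapply(seq_along(reports), function(k) {
    pi <- reports[[k]]$per_image
    data.frame(fold = k, sample_id = pi$sample_id,
               gt_count = pi$gt_count, pred_count = pi$pred_count)
  }))
  structure(list(by_fold = by_fold, summary = summary_tab, counts = counts),
            class = "fp_cv_summary")
}

#' @export
print.fp_cv_summary <- function(x, ...) {
  cat("<fp_cv_summary>", nrow(x$by_fold), "fold(s)\n")
  s <- x$summary
  for (m in c("mae", "ssim", "dice", "tp_rate_pct", "un_rate_pct", "up_rate_pct")) {
    r <- s[s$metric == m, ]
    if (nrow(r)) cat(sprintf("  %-22s %8.3f +/- %.3f\n", m, r$mean, r$sd))
  }
  invisible(x)
}
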