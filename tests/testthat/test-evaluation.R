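# Metrics, point matching and rate computation.

test_that("MAE is zero on identity, symmetric, and exact on constant offsets", {
  set.seed(1)
  a <- matrix(runif(256), 16)
  b <- matrix(runif(256), 16)
  expect_equal(mae_metric(a, a), 0)
  expect_equal(mae_metric(a, b), mae_metric(b, a))
  expect_equal(mae_metric(matrix(0, 8, 8), matrix(0.1, 8, 8)), 0.1)
  expect_error(mae_metric(a, matrix(0, 4, 4)), "shapes")
})

test_that("SSIM satisfies its closed forms and definitional maximum", {
  set.seed(2)
  a <- matrix(runif(256), 16)
  expect_equal(ssim_metric(a, a), 1, tolerance = 1e-9)
  # zero-variance closed form for two constant maps
  c1 <- 0.3; c2 <- 0.8; C1 <- 1e-4
  expect_equal(ssim_metric(matrix(c1, 12, 12), matrix(c2, 12, 12)),
               (2 * c1 * c2 + C1) / (c1^2 + c2^2 + C1), tolerance = 1e-9)
  # inverted high-variance pattern is anticorrelated
  hv <- matrix(rep(c(0.05, 0.95), length.out = 256), 16)
  expect_lt(ssim_metric(1 - hv, hv), 0)
})

test_that("SSIM agrees with a direct per-window evaluation", {
  # independent oracle: explicit loops over Gaussian windows on a small map
  set.seed(5)
  n <- 16
  x <- matrix(runif(n * n), n)
  y <- pmin(pmax(x + matrix(rnorm(n * n, sd = 0.2), n), 0), 1)
  h <- 5
  kern1 <- exp(-((-h:h)^2) / (2 * 1.5^2)); kern1 <- kern1 / sum(kern1)
  kern2 <- outer(kern1, kern1)
  # symmetric (edge-including) reflection, matching the filter's padding
  refl <- function(i, n) {
    x <- (i - 1) %% (2 * n)
    x <- ifelse(x < 0, x + 2 * n, x)
    ifelse(x >= n, 2 * n - 1 - x, x) + 1
  }
  C1 <- 1e-4; C2 <- 9e-4
  vals <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    ri <- refl(i + (-h:h), n); ci <- refl(j + (-h:h), n)
    wx <- x[ri, ci]; wy <- y[ri, ci]
    mx <- sum(kern2 * wx); my <- sum(kern2 * wy)
    vx <- sum(kern2 * wx^2) - mx^2; vy <- sum(kern2 * wy^2) - my^2
    cxy <- sum(kern2 * wx * wy) - mx * my
    vals[i, j] <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  expect_equal(ssim_metric(x, y), mean(vals), tolerance = 1e-12)
})

test_that("Dice handles identity, disjoint and enumerated overlaps", {
  m <- matrix(0, 8, 8); m[2:3, 2:3] <- 1
  expect_equal(dice_metric(m, m), 1)
  m2 <- matrix(0, 8, 8); m2[6:7, 6:7] <- 1
  expect_equal(dice_metric(m, m2), 0)
  # |A| = 4, |B| = 4, |A intersect B| = 2 -> 0.5
  a <- matrix(0, 8, 8); a[1, 1:4] <- 1
  b <- matrix(0, 8, 8); b[1, 3:6] <- 1
  expect_equal(dice_metric(a, b), 0.5)
  expect_equal(dice_metric(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
})

test_that("match_points handles simple configurations", {
  oc <- match_points(c(5, 5), c(6, 5), radius = 3)
  expect_equal(c(oc$tp, oc$up, oc$un), c(1L, 0L, 0L))

  oc <- match_points(c(5, 5), NULL, radius = 3)
  expect_equal(c(oc$tp, oc$up, oc$un), c(0L, 0L, 1L))

  # one prediction between two ground-truth points: exactly one TP either way
  oc <- match_points(rbind(c(0, 0), c(4, 0)), c(2, 0), radius = 3)
  expect_equal(c(oc$tp, oc$up, oc$un), c(1L, 0L, 1L))

  # assignment is optimal, not greedy: nearest-first would lose a match here
  oc <- match_points(rbind(c(0, 0), c(3, 0)), rbind(c(1, 0), c(-2, 0)), radius = 3)
  expect_equal(oc$tp, 2L)
})

test_that("match_points equals exhaustive assignment enumeration", {
  set.seed(123)
  for (rep in 1:120) {
    ngt <- sample(0:7, 1); npred <- sample(0:7, 1)
    gt <- if (ngt) cbind(runif(ngt, 0, 20), runif(ngt, 0, 20)) else NULL
    pred <- if (npred) cbind(runif(npred, 0, 20), runif(npred, 0, 20)) else NULL
    radius <- runif(1, 1, 8)
    oc <- match_points(gt, pred, radius)
    want <- brute_force_match(gt, pred, radius)
    expect_equal(oc$tp, want$tp)
    if (oc$tp > 0)
      expect_equal(sum(oc$matched_pairs$distance), want$dist, tolerance = 1e-9)
    expect_true(all(oc$matched_pairs$distance <= radius))
  }
})

test_that("TP/UP/UN conservation holds on random instances", {
  set.seed(321)
  for (rep in 1:60) {
    ngt <- sample(0:20, 1); npred <- sample(0:20, 1)
    gt <- if (ngt) cbind(runif(ngt, 0, 60), runif(ngt, 0, 60)) else NULL
    pred <- if (npred) cbind(runif(npred, 0, 60), runif(npred, 0, 60)) else NULL
    oc <- match_points(gt, pred, radius = 5)
    expect_identical(oc$tp + oc$un, ngt)
    expect_identical(oc$tp + oc$up, npred)
  }
})

test_that("detection rates reproduce the three published formulas", {
  r <- detection_rates(list(tp = 8, up = 2, un = 2))
  expect_equal(r$tp_rate_pct, 80)
  expect_equal(r$accurate_count_pct, 80)
  expect_equal(r$complete_accuracy_pct, 100 * 8 / 12)
  expect_equal(r$tp_rate_pct + r$un_rate_pct, 100)

  perfect <- detection_rates(list(tp = 9, up = 0, un = 0))
  expect_equal(unlist(perfect[c(1, 4, 5)]), c(100, 100, 100), ignore_attr = TRUE)

  zero <- detection_rates(list(tp = 0, up = 5, un = 10))
  expect_equal(zero$tp_rate_pct, 0)
  expect_equal(zero$complete_accuracy_pct, 0)

  undef <- detection_rates(list(tp = 0, up = 0, un = 0))
  expect_true(is.na(undef$tp_rate_pct))
  expect_true(is.na(undef$accurate_count_pct))
})

test_that("aggregate_runs averages fold-normalized rates and exports counts", {
  mk_eval <- function(tp, up, un, n_img = 2) {
    per_image <- data.frame(sample_id = paste0("s", seq_len(n_img)),
                            mae = 0.01, ssim = 0.9, dice = 0.8,
                            gt_count = (tp + un) / n_img,
                            pred_count = (tp + up) / n_img,
                            tp = tp / n_img, up = up / n_img, un = un / n_img)
    structure(list(per_image = per_image), class = "fp_eval")
  }
  agg <- aggregate_runs(list(mk_eval(8, 2, 2), mk_eval(6, 2, 4)))
  expect_equal(agg$by_fold$tp_rate_pct, c(80, 60))
  s <- agg$summary
  expect_equal(s$mean[s$metric == "tp_rate_pct"], 70)
  expect_equal(s$sd[s$metric == "tp_rate_pct"], sd(c(80, 60)))
  expect_equal(nrow(agg$counts), 4L)

  one <- aggregate_runs(list(mk_eval(8, 2, 2)))
  expect_equal(one$summary$sd[one$summary$metric == "tp_rate_pct"], 0)
})
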