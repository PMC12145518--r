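# Architecture specifications, parameter accounting and the network engine.

test_that("the three specifications match their published layouts", {
  cl <- classic_unet_spec(3L)
  expect_equal(cl$encoder_filters, c(64L, 128L, 256L, 512L))
  expect_equal(cl$middle_filters, 1024L)
  expect_equal(cl$decoder_filters, rev(cl$encoder_filters))
  expect_false(cl$use_batch_norm)
  expect_equal(cl$dropout_rate, 0)

  op <- optimized_unet_spec(3L)
  expect_equal(op$encoder_filters, c(64L, 64L, 128L, 256L))
  expect_equal(op$middle_filters, 512L)
  expect_true(op$use_batch_norm)
  expect_gt(op$dropout_rate, 0)

  mr <- multires_unet_spec(3L)
  expect_equal(mr$alpha, 1.67)
  expect_equal(mr$base_filters, 32L)

  for (s in list(cl, op, mr)) expect_equal(s$final_activation, "linear")
})

test_that("every compiled network ends in a linear single-channel 1x1 head", {
  for (mk in list(classic_unet_spec, optimized_unet_spec, multires_unet_spec)) {
    spec <- mk(3L)
    net <- fungiform:::compile_spec(spec)
    head <- net$nodes[[net$out]]
    expect_equal(head$op, "conv")       # no activation node after it
    expect_equal(head$k, 1L)
    expect_equal(head$cout, 1L)
  }
})

test_that("MultiRes blocks and residual skip paths have the cited structure", {
  net <- fungiform:::compile_spec(multires_unet_spec(3L))
  nodes <- net$nodes
  count_convs <- function(tag, k) {
    sum(vapply(nodes, function(nd)
      identical(nd$op, "conv") && identical(nd$tag, tag) && nd$k == k, TRUE))
  }
  for (s in 1:4) {
    expect_equal(count_convs(paste0("enc", s), 3L), 3L)  # three chained 3x3
    expect_equal(count_convs(paste0("enc", s), 1L), 1L)  # one 1x1 shortcut
  }
  # residual path lengths shrink with depth: 4, 3, 2, 1 units
  for (s in 1:4)
    expect_equal(count_convs(paste0("respath", s), 3L), 5L - s)
})

test_that("parameter counts follow the closed forms", {
  # single same-padded 3x3 convolution, 3 -> 64 channels, with bias
  g <- fungiform:::ng_new()
  x <- fungiform:::ng_add(g, "input", integer(), 3L)
  fungiform:::ng_conv(g, x, 64L)
  nd <- g$nodes[[2]]
  expect_equal(sum(vapply(nd$pshape, prod, 1)), 3 * 3 * 3 * 64 + 64)

  # the optimized variant is the leaner network
  expect_lt(count_parameters(optimized_unet_spec(3L)),
            count_parameters(classic_unet_spec(3L)))

  # doubling every width of the bias-dominant-free classic spec scales the
  # kernel terms by ~4 (first layer and biases break exactness)
  ratio <- count_parameters(classic_unet_spec(3L, width_scale = 2)) /
    count_parameters(classic_unet_spec(3L))
  expect_gt(ratio, 3.9)
  expect_lt(ratio, 4.1)
})

test_that("instantiation is deterministic and honors the shape contract", {
  spec <- optimized_unet_spec(3L, dropout_rate = 0.2, width_scale = 0.05)
  m1 <- instantiate(spec, seed = 4)
  m2 <- instantiate(spec, seed = 4)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  img <- pmin(pmax(img, 0), 1)
  p1 <- predict(m1, img)
  p2 <- predict(m2, img)
  expect_identical(p1, p2)            # same seed, inference mode: identical
  expect_equal(dim(p1), c(64, 64))    # one channel, input spatial shape

  # non-divisible sizes are padded internally and cropped back
  img250 <- array(runif(250 * 250 * 3), dim = c(250, 250, 3))
  expect_equal(dim(predict(m1, img250)), c(250, 250))

  expect_error(predict(m1, array(0.5, dim = c(32, 32, 1))), "channels")
})

test_that("analytic gradients agree with finite differences", {
  spec <- optimized_unet_spec(1L, dropout_rate = 0, width_scale = 0.05)
  m <- instantiate(spec, seed = 2)
  set.seed(9)
  x <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  gt <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  fw <- fungiform:::net_forward(m$nodes, m$out, x, training = TRUE)
  grads <- fungiform:::net_backward(m$nodes, m$out, fw, 2 * (fw$out - gt) / length(gt))
  loss <- function(nodes) {
    mean((fungiform:::net_forward(nodes, m$out, x, training = TRUE)$out - gt)^2)
  }
  eps <- 1e-4
  n_checked <- 0
  for (i in seq_along(m$nodes)) {
    if (is.null(grads[[i]]) || m$nodes[[i]]$op == "bn") next
    for (pn in names(grads[[i]])) {
      p <- m$nodes[[i]]$params[[pn]]
      k <- sample(length(p), 1)
      ana <- grads[[i]][[pn]][k]
      if (abs(ana) < 1e-7) next  # bias-into-BN gradients vanish identically
      n2 <- m$nodes
      n2[[i]]$params[[pn]][k] <- p[k] + eps
      lp <- loss(n2)
      n2[[i]]$params[[pn]][k] <- p[k] - eps
      lm <- loss(n2)
      num <- (lp - lm) / (2 * eps)
      # mixed tolerance: absolute floor absorbs finite-difference noise on
      # small-magnitude gradients
      expect_lt(abs(num - ana), 1e-6 + 1e-3 * (abs(num) + abs(ana)))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("dropout is active in training mode and silent at inference", {
  spec <- optimized_unet_spec(3L, dropout_rate = 0.5, width_scale = 0.05)
  m <- instantiate(spec, seed = 1)
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3, 1))
  set.seed(1); t1 <- fungiform:::net_forward(m$nodes, m$out, x, training = TRUE)$out
  set.seed(2); t2 <- fungiform:::net_forward(m$nodes, m$out, x, training = TRUE)$out
  expect_gt(max(abs(t1 - t2)), 0)     # stochastic under dropout
  i1 <- fungiform:::net_forward(m$nodes, m$out, x, training = FALSE)$out
  i2 <- fungiform:::net_forward(m$nodes, m$out, x, training = FALSE)$out
  expect_identical(i1, i2)            # deterministic at inference
})
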