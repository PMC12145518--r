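#' @useDynLib fungiform, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- computation-graph construction ------------------------------------------
#
# A network is a flat list of nodes in topological order. Each node records its
# op, the ids of its input nodes, its output channel count, parameter shapes
# and (after instantiation) the parameter arrays themselves. Supported ops:
# input, conv (same-padded k x k), convT (2x2 stride-2 transposed conv), pool
# (2x2 max), relu, bn, dropout, concat (channel-wise), add.

ng_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

ng_add <- function(g, op, inputs = integer(), cout, ...) {
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- c(list(id = id, op = op, inputs = as.integer(inputs),
                          cout = as.integer(cout)), list(...))
  id
}

ng_conv <- function(g, x, cout, k = 3L, tag = "") {
  cin <- g$nodes[[x]]$cout
  ng_add(g, "conv", x, cout, k = as.integer(k), cin = cin, tag = tag,
         pshape = list(w = c(k, k, cin, cout), b = cout))
}

ng_convT <- function(g, x, cout, tag = "") {
  cin <- g$nodes[[x]]$cout
  ng_add(g, "convT", x, cout, cin = cin, tag = tag,
         pshape = list(w = c(2L, 2L, cin, cout), b = cout))
}

ng_bn <- function(g, x, tag = "") {
  c <- g$nodes[[x]]$cout
  ng_add(g, "bn", x, c, tag = tag, pshape = list(gamma = c, beta = c))
}

ng_relu    <- function(g, x) ng_add(g, "relu", x, g$nodes[[x]]$cout)
ng_pool    <- function(g, x) ng_add(g, "pool", x, g$nodes[[x]]$cout)
ng_dropout <- function(g, x, rate) ng_add(g, "dropout", x, g$nodes[[x]]$cout, rate = rate)
ng_concat  <- function(g, xs) {
  ng_add(g, "concat", xs, sum(vapply(xs, function(i) g$nodes[[i]]$cout, 1L)))
}
ng_add_op <- function(g, a, b) {
  stopifnot(g$nodes[[a]]$cout == g$nodes[[b]]$cout)
  ng_add(g, "add", c(a, b), g$nodes[[a]]$cout)
}

# conv [+ bn] + relu
ng_cbr <- function(g, x, f, k = 3L, batch_norm = FALSE, tag = "") {
  x <- ng_conv(g, x, f, k = k, tag = tag)
  if (batch_norm) x <- ng_bn(g, x, tag = tag)
  ng_relu(g, x)
}

# ---- architecture compilers --------------------------------------------------

# Plain encoder-decoder (classic and optimized U-Net share this shape).
compile_vanilla_unet <- function(spec) {
  g <- ng_new()
  x <- ng_add(g, "input", integer(), spec$input_channels)
  bn <- spec$use_batch_norm
  dr <- spec$dropout_rate
  skips <- integer()
  for (s in seq_along(spec$encoder_filters)) {
    f <- spec$encoder_filters[s]
    tag <- paste0("enc", s)
    x <- ng_cbr(g, x, f, batch_norm = bn, tag = tag)
    x <- ng_cbr(g, x, f, batch_norm = bn, tag = tag)
    if (dr > 0) x <- ng_dropout(g, x, dr)
    skips[s] <- x
    x <- ng_pool(g, x)
  }
  tag <- "middle"
  x <- ng_cbr(g, x, spec$middle_filters, batch_norm = bn, tag = tag)
  x <- ng_cbr(g, x, spec$middle_filters, batch_norm = bn, tag = tag)
  if (dr > 0) x <- ng_dropout(g, x, spec$middle_dropout_rate)
  for (s in rev(seq_along(spec$encoder_filters))) {
    f <- spec$decoder_filters[length(spec$decoder_filters) - s + 1L]
    tag <- paste0("dec", s)
    x <- ng_convT(g, x, f, tag = tag)
    x <- ng_concat(g, c(x, skips[s]))
    x <- ng_cbr(g, x, f, batch_norm = bn, tag = tag)
    x <- ng_cbr(g, x, f, batch_norm = bn, tag = tag)
    if (dr > 0) x <- ng_dropout(g, x, dr)
  }
  out <- ng_conv(g, x, 1L, k = 1L, tag = "head")  # linear regression head
  list(nodes = g$nodes, out = out)
}

# MultiRes block: three chained 3x3 convolutions whose outputs are concatenated,
# plus a 1x1 shortcut projection added to the concatenation.
ng_multires_block <- function(g, x, w_total, tag) {
  f1 <- max(1L, floor(w_total / 6))
  f2 <- max(1L, floor(w_total / 3))
  f3 <- max(1L, floor(w_total / 2))
  fo <- f1 + f2 + f3
  sc <- ng_conv(g, x, fo, k = 1L, tag = tag)
  sc <- ng_bn(g, sc, tag = tag)
  c1 <- ng_cbr(g, x, f1, batch_norm = TRUE, tag = tag)
  c2 <- ng_cbr(g, c1, f2, batch_norm = TRUE, tag = tag)
  c3 <- ng_cbr(g, c2, f3, batch_norm = TRUE, tag = tag)
  cat <- ng_concat(g, c(c1, c2, c3))
  cat <- ng_bn(g, cat, tag = tag)
  out <- ng_add_op(g, cat, sc)
  out <- ng_relu(g, out)
  ng_bn(g, out, tag = tag)
}

# Residual skip path: n_units repeats of [3x3 conv + 1x1 shortcut, added].
ng_res_path <- function(g, x, f, n_units, tag) {
  for (u in seq_len(n_units)) {
    sc <- ng_conv(g, x, f, k = 1L, tag = tag)
    sc <- ng_bn(g, sc, tag = tag)
    m  <- ng_conv(g, x, f, k = 3L, tag = tag)
    m  <- ng_bn(g, m, tag = tag)
    x  <- ng_relu(g, ng_add_op(g, m, sc))
  }
  x
}

compile_multires_unet <- function(spec) {
  g <- ng_new()
  x <- ng_add(g, "input", integer(), spec$input_channels)
  base  <- spec$base_filters
  alpha <- spec$alpha
  n_stages <- 4L
  skips <- integer()
  for (s in seq_len(n_stages)) {
    w_total <- alpha * base * 2^(s - 1)
    x <- ng_multires_block(g, x, w_total, tag = paste0("enc", s))
    skips[s] <- ng_res_path(g, x, max(1L, round(base * 2^(s - 1))),
                            n_units = n_stages - s + 1L, tag = paste0("respath", s))
    x <- ng_pool(g, x)
  }
  x <- ng_multires_block(g, x, alpha * base * 2^n_stages, tag = "middle")
  for (s in rev(seq_len(n_stages))) {
    f <- max(1L, round(base * 2^(s - 1)))
    x <- ng_convT(g, x, f, tag = paste0("dec", s))
    x <- ng_concat(g, c(x, skips[s]))
    x <- ng_multires_block(g, x, alpha * base * 2^(s - 1), tag = paste0("dec", s))
  }
  out <- ng_conv(g, x, 1L, k = 1L, tag = "head")
  list(nodes = g$nodes, out = out)
}

compile_spec <- function(spec) {
  switch(spec$architecture,
         classic_unet   = compile_vanilla_unet(spec),
         optimized_unet = compile_vanilla_unet(spec),
         multires_unet  = compile_multires_unet(spec),
         stop("unknown architecture: ", spec$architecture))
}

# ---- instantiation -----------------------------------------------------------

init_params <- function(nodes, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (is.null(nd$pshape)) next
    if (nd$op %in% c("conv", "convT")) {
      fan_in <- prod(nd$pshape$w[-length(nd$pshape$w)])
      # He-normal before rectifiers; the linear regression head is
      # initialized near zero so the initial prediction is the empty map,
      # the usual choice for heatmap-regression output layers
      sdw <- if (identical(nd$tag, "head")) 1e-2 else sqrt(2 / fan_in)
      w <- array(stats::rnorm(prod(nd$pshape$w), sd = sdw), dim = nd$pshape$w)
      nodes[[i]]$params <- list(w = w, b = numeric(nd$pshape$b))
    } else if (nd$op == "bn") {
      nodes[[i]]$params <- list(gamma = rep(1, nd$pshape$gamma),
                                beta  = rep(0, nd$pshape$beta))
      nodes[[i]]$state <- list(rm = rep(0, nd$cout), rv = rep(1, nd$cout))
    }
  }
  nodes
}

# ---- forward / backward ------------------------------------------------------

bn_stats <- function(x, eps = 1e-5) {
  st <- channel_stats(x)
  list(mean = st$mean, var = st$var, inv = 1 / sqrt(st$var + eps))
}

net_forward <- function(nodes, out_id, x, training = FALSE) {
  acts <- vector("list", length(nodes))
  extras <- vector("list", length(nodes))
  for (nd in nodes) {
    y <- switch(nd$op,
      input = x,
      conv  = conv2d_fwd(acts[[nd$inputs]], nd$params$w, nd$params$b),
      convT = convT2_fwd(acts[[nd$inputs]], nd$params$w, nd$params$b),
      pool  = {
        r <- maxpool2_fwd(acts[[nd$inputs]])
        extras[[nd$id]] <- r$idx
        r$y
      },
      relu  = relu_fwd(acts[[nd$inputs]]),
      bn = {
        a <- acts[[nd$inputs]]
        if (training) {
          st <- bn_stats(a)
          extras[[nd$id]] <- st
          bn_apply(a, st$mean, st$inv, nd$params$gamma, nd$params$beta)
        } else {
          bn_apply(a, nd$state$rm, 1 / sqrt(nd$state$rv + 1e-5),
                   nd$params$gamma, nd$params$beta)
        }
      },
      dropout = {
        a <- acts[[nd$inputs]]
        if (training && nd$rate > 0) {
          mask <- (stats::runif(length(a)) >= nd$rate) / (1 - nd$rate)
          dim(mask) <- dim(a)
          extras[[nd$id]] <- mask
          a * mask
        } else a
      },
      concat = {
        ins <- lapply(nd$inputs, function(i) acts[[i]])
        d1 <- dim(ins[[1]])
        cs <- vapply(ins, function(a) dim(a)[3], 1)
        y <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
        off <- 0L
        for (a in ins) {
          y[, , off + seq_len(dim(a)[3]), ] <- a
          off <- off + dim(a)[3]
        }
        y
      },
      add = acts[[nd$inputs[1]]] + acts[[nd$inputs[2]]],
      stop("bad op ", nd$op))
    acts[[nd$id]] <- y
  }
  list(out = acts[[out_id]], acts = acts, extras = extras)
}

net_backward <- function(nodes, out_id, fw, dy) {
  acts <- fw$acts
  extras <- fw$extras
  dacts <- vector("list", length(nodes))
  grads <- vector("list", length(nodes))
  dacts[[out_id]] <- dy
  push <- function(dacts, id, g) {
    if (is.null(dacts[[id]])) dacts[[id]] <- g else dacts[[id]] <- dacts[[id]] + g
    dacts
  }
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    d_out <- dacts[[i]]
    if (is.null(d_out) || nd$op == "input") next
    switch(nd$op,
      conv = {
        r <- conv2d_bwd(acts[[nd$inputs]], nd$params$w, d_out)
        grads[[i]] <- list(w = r$dw, b = r$db)
        dacts <- push(dacts, nd$inputs, r$dx)
      },
      convT = {
        r <- convT2_bwd(acts[[nd$inputs]], nd$params$w, d_out)
        grads[[i]] <- list(w = r$dw, b = r$db)
        dacts <- push(dacts, nd$inputs, r$dx)
      },
      pool = {
        din <- dim(acts[[nd$inputs]])
        dacts <- push(dacts, nd$inputs, maxpool2_bwd(d_out, extras[[i]], din[1], din[2]))
      },
      relu = dacts <- push(dacts, nd$inputs, relu_bwd(d_out, acts[[i]])),
      bn = {
        batch_mode <- !is.null(extras[[i]])
        st <- if (batch_mode) extras[[i]] else
          list(mean = nd$state$rm, inv = 1 / sqrt(nd$state$rv + 1e-5))
        r <- bn_bwd(acts[[nd$inputs]], d_out, st$mean, st$inv,
                    nd$params$gamma, batch_mode)
        grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
        dacts <- push(dacts, nd$inputs, r$dx)
      },
      dropout = {
        g <- if (is.null(extras[[i]])) d_out else d_out * extras[[i]]
        dacts <- push(dacts, nd$inputs, g)
      },
      concat = {
        off <- 0L
        for (src in nd$inputs) {
          cs <- nodes[[src]]$cout
          dacts <- push(dacts, src, d_out[, , off + seq_len(cs), , drop = FALSE])
          off <- off + cs
        }
      },
      add = {
        dacts <- push(dacts, nd$inputs[1], d_out)
        dacts <- push(dacts, nd$inputs[2], d_out)
      })
    dacts[[i]] <- NULL  # free as we go
  }
  grads
}

# Update batch-norm running statistics from a training forward pass.
bn_update_running <- function(nodes, extras, momentum = 0.99) {
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$op == "bn" && !is.null(extras[[i]])) {
      st <- extras[[i]]
      nodes[[i]]$state$rm <- momentum * nodes[[i]]$state$rm + (1 - momentum) * st$mean
      nodes[[i]]$state$rv <- momentum * nodes[[i]]$state$rv + (1 - momentum) * st$var
    }
  }
  nodes
}

# ---- Adam --------------------------------------------------------------------

adam_new <- function(nodes) {
  st <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    if (!is.null(nodes[[i]]$params)) {
      st[[i]] <- lapply(nodes[[i]]$params, function(p) list(m = p * 0, v = p * 0))
    }
  }
  list(state = st, t = 0L)
}

adam_step <- function(nodes, grads, adam, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  adam$t <- adam$t + 1L
  bc1 <- 1 - beta1^adam$t
  bc2 <- 1 - beta2^adam$t
  for (i in seq_along(nodes)) {
    if (is.null(grads[[i]])) next
    for (pn in names(grads[[i]])) {
      g <- grads[[i]][[pn]]
      s <- adam$state[[i]][[pn]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      adam$state[[i]][[pn]] <- s
      nodes[[i]]$params[[pn]] <- nodes[[i]]$params[[pn]] -
        lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    }
  }
  list(nodes = nodes, adam = adam)
}
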