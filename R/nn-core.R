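# Minimal layer primitives (forward + reverse-mode backward) on which the
# U-Net generator and the patch critic are assembled. Activations are numeric
# arrays with dim (H, W, C, N); see src/nn_kernels.cpp for the weight layout.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 3 || length(d) > 4)
    abort("expected an (H, W, C) or (H, W, C, N) array")
  if (length(d) == 3) dim(x) <- c(d, 1L)
  x
}

nn_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  K <- k * k * cin
  # He initialization, matched to the ReLU family used throughout
  w <- matrix(rnorm(cout * K, sd = sqrt(2 / K)), cout, K)
  list(kind = "conv", par = list(w = w, b = numeric(cout)),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad))
}

nn_upconv <- function(cin, cout) {
  w <- matrix(rnorm(cout * 4L * cin, sd = sqrt(2 / (4 * cin))), cout, 4L * cin)
  list(kind = "upconv", par = list(w = w, b = numeric(cout)))
}

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(kind = "bn", par = list(gamma = rep(1, c), beta = rep(0, c)),
       buf = list(rm = rep(0, c), rv = rep(1, c)),
       eps = eps, momentum = momentum)
}

conv_fw <- function(layer, x) {
  cpp_conv2d_forward(x, layer$par$w, layer$par$b, layer$k, layer$stride,
                     layer$pad)
}

conv_bw <- function(layer, x, dy, need_dx = TRUE) {
  cpp_conv2d_backward(x, layer$par$w, dy, layer$k, layer$stride, layer$pad,
                      need_dx)
}

upconv_fw <- function(layer, x) cpp_upconv2_forward(x, layer$par$w, layer$par$b)

upconv_bw <- function(layer, x, dy, need_dx = TRUE) {
  cpp_upconv2_backward(x, layer$par$w, dy, need_dx)
}

relu_fw <- function(x) cpp_relu_forward(x)

lrelu_fw <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

bn_fw <- function(layer, x, train) {
  if (train) {
    st <- cpp_bn_stats(x)
    mu <- st$mu; v <- st$var
    layer$buf$rm <- (1 - layer$momentum) * layer$buf$rm + layer$momentum * mu
    layer$buf$rv <- (1 - layer$momentum) * layer$buf$rv + layer$momentum * v
  } else {
    mu <- layer$buf$rm; v <- layer$buf$rv
  }
  invstd <- 1 / sqrt(v + layer$eps)
  if (train) {
    xhat <- cpp_channel_affine(x, invstd, -mu * invstd)
    y <- cpp_channel_affine(xhat, layer$par$gamma, layer$par$beta)
    cache <- list(xhat = xhat, invstd = invstd)
  } else {
    gi <- layer$par$gamma * invstd
    y <- cpp_channel_affine(x, gi, layer$par$beta - gi * mu)
    cache <- NULL
  }
  list(y = y, layer = layer, cache = cache)
}

bn_bw <- function(layer, cache, dy) {
  cpp_bn_backward(cache$xhat, dy, layer$par$gamma, cache$invstd)
}

# conv -> ReLU -> BN, twice (the down/up block of the generator)
block_make <- function(cin, cmid, cout) {
  list(conv1 = nn_conv(cin, cmid, 3L), bn1 = nn_bn(cmid),
       conv2 = nn_conv(cmid, cout, 3L), bn2 = nn_bn(cout))
}

block_fw <- function(blk, x, train, keep = train) {
  c1 <- conv_fw(blk$conv1, x)
  r1 <- relu_fw(c1)
  o1 <- bn_fw(blk$bn1, r1, train)
  blk$bn1 <- o1$layer
  c2 <- conv_fw(blk$conv2, o1$y)
  r2 <- relu_fw(c2)
  o2 <- bn_fw(blk$bn2, r2, train)
  blk$bn2 <- o2$layer
  cache <- if (keep) {
    list(x = x, r1 = r1, bn1 = o1$cache, x2 = o1$y, r2 = r2, bn2 = o2$cache)
  }
  list(y = o2$y, blk = blk, cache = cache)
}

block_bw <- function(blk, cache, dy, need_dx = TRUE) {
  g2 <- bn_bw(blk$bn2, cache$bn2, dy)
  dr2 <- cpp_relu_backward(g2$dx, cache$r2)
  b2 <- conv_bw(blk$conv2, cache$x2, dr2, need_dx = TRUE)
  g1 <- bn_bw(blk$bn1, cache$bn1, b2$dx)
  dr1 <- cpp_relu_backward(g1$dx, cache$r1)
  b1 <- conv_bw(blk$conv1, cache$x, dr1, need_dx = need_dx)
  list(dx = if (need_dx) b1$dx,
       grads = list(conv1 = list(w = b1$dw, b = b1$db),
                    bn1 = list(gamma = g1$gamma, beta = g1$beta),
                    conv2 = list(w = b2$dw, b = b2$db),
                    bn2 = list(gamma = g2$gamma, beta = g2$beta)))
}

# ---- parameter-tree utilities -------------------------------------------

# Walk a nested layer structure and apply f(path, leaf) to every trainable
# parameter array (the entries of each layer's $par).
walk_params <- function(node, path, f) {
  if (!is.list(node)) return(invisible())
  if (!is.null(node$par)) {
    for (nm in names(node$par)) f(c(path, nm), node$par[[nm]])
    return(invisible())
  }
  for (nm in names(node)) walk_params(node[[nm]], c(path, nm), f)
}

flatten_params <- function(layers) {
  out <- list()
  walk_params(layers, character(), function(path, leaf) {
    out[[paste(path, collapse = ".")]] <<- leaf
  })
  out
}

# Map a flat named list of updated arrays back into the nested structure.
assign_params <- function(layers, flat) {
  for (nm in names(flat)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    n <- length(path)
    idx <- c(path[-n], "par", path[n])
    layers[[idx]] <- flat[[nm]]
  }
  layers
}

flatten_grads <- function(grads) {
  out <- list()
  rec <- function(node, path) {
    if (is.numeric(node)) {
      out[[paste(path, collapse = ".")]] <<- node
      return(invisible())
    }
    for (nm in names(node)) rec(node[[nm]], c(path, nm))
  }
  rec(grads, character())
  out
}

add_flat <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

scale_flat <- function(a, s) lapply(a, function(g) g * s)

# ---- Adam ---------------------------------------------------------------

adam_init <- function(flat_params) {
  list(t = 0L,
       m = lapply(flat_params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(flat_params, function(p) array(0, dim = dim(p) %||% length(p))))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}
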