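#' Generator (U-Net) configuration
#'
#' The generator is a U-Net mapping a 3-plane brightfield stack to the five
#' fluorescent channels. The down-sampling path has `levels` convolutional
#' blocks, the first with `base_filters` filters and doubling at every level
#' (32, 64, ..., 1024 at the defaults); each block applies `convs_per_block`
#' kernel-3, stride-1, pad-1 convolutions, each followed by ReLU then batch
#' normalization. 2x2 max pooling (stride 2) sits between blocks; the
#' up-sampling path is symmetric, using kernel-2 stride-2 transposed
#' convolutions and skip concatenations, and the final layer is a plain 1x1
#' convolution with no activation or normalization. With the defaults the
#' network has about 31 million trainable parameters.
#'
#' @param in_channels,out_channels Input/output channel counts (3 brightfield
#'   planes in, 5 fluorescent channels out).
#' @param levels Number of resolution levels (blocks on the down path).
#' @param base_filters Filters in the first block; doubled per level.
#' @param convs_per_block Convolutions per block (2 = classic U-Net; this
#'   value reproduces the 31e6 parameter total and is pinned by test).
#' @return A `bp_generator_config` list.
#' @seealso [build_generator()], [count_trainable_parameters()]
#' @export
generator_config <- function(in_channels = 3L, out_channels = 5L,
                             levels = 6L, base_filters = 32L,
                             convs_per_block = 2L) {
  if (levels < 2) abort("generator_config: levels must be >= 2")
  if (convs_per_block != 2L)
    abort("generator_config: only convs_per_block = 2 is implemented")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 convs_per_block = 2L,
                 filters = as.integer(base_filters * 2^(0:(levels - 1)))),
            class = "bp_generator_config")
}

#' Build the U-Net generator
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return A `bp_generator` object holding the layer tree and config. Use
#'   [generator_predict()] for inference and [count_trainable_parameters()]
#'   for introspection.
#' @examples
#' gen <- build_generator(generator_config(levels = 3, base_filters = 4), seed = 1)
#' y <- generator_predict(gen, array(rnorm(32 * 32 * 3), c(32, 32, 3)))
#' dim(y)
#' @export
build_generator <- function(config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- config$filters
  L <- config$levels
  layers <- list()
  cin <- config$in_channels
  for (l in seq_len(L)) {
    layers[[paste0("d", l)]] <- block_make(cin, f[l], f[l])
    cin <- f[l]
  }
  for (l in rev(seq_len(L - 1))) {
    layers[[paste0("u", l)]] <- c(
      list(up = nn_upconv(f[l + 1], f[l])),
      block_make(2L * f[l], f[l], f[l]))
  }
  layers$final <- nn_conv(f[1], config$out_channels, 1L, pad = 0L)
  structure(list(config = config, layers = layers), class = "bp_generator")
}

#' @export
print.bp_generator <- function(x, ...) {
  cat(sprintf("<bp_generator> U-Net %d->%d channels, %d levels (%s filters), %s trainable parameters\n",
              x$config$in_channels, x$config$out_channels, x$config$levels,
              paste(x$config$filters, collapse = "/"),
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

# Spatial divisibility required by the pooling pyramid.
generator_stride <- function(config) 2L^(config$levels - 1L)

check_generator_input <- function(gen, x) {
  d <- dim(x)
  s <- generator_stride(gen$config)
  if (d[1] %% s != 0 || d[2] %% s != 0)
    abort(sprintf(
      "generator input size %dx%d must be divisible by 2^(levels-1) = %d",
      d[1], d[2], s))
  if (d[3] != gen$config$in_channels)
    abort(sprintf("generator expects %d input channels, got %d",
                  gen$config$in_channels, d[3]))
}

# Full forward pass. With train = TRUE batch-norm uses batch statistics,
# running averages are updated and caches for the backward pass are kept.
generator_forward <- function(gen, x, train = FALSE) {
  x <- as_batch(x)
  check_generator_input(gen, x)
  L <- gen$config$levels
  caches <- list()
  skips <- list()
  h <- x
  for (l in seq_len(L)) {
    nm <- paste0("d", l)
    o <- block_fw(gen$layers[[nm]], h, train)
    gen$layers[[nm]] <- o$blk
    caches[[nm]] <- o$cache
    h <- o$y
    if (l < L) {
      skips[[l]] <- h
      p <- cpp_maxpool2_forward(h)
      caches[[paste0("p", l)]] <- list(idx = p$idx, in_dim = dim(h))
      h <- p$y
    }
  }
  for (l in rev(seq_len(L - 1))) {
    nm <- paste0("u", l)
    blk <- gen$layers[[nm]]
    up_in <- h
    u <- upconv_fw(blk$up, h)
    h <- abind4(skips[[l]], u)
    o <- block_fw(blk, h, train)
    gen$layers[[nm]] <- o$blk
    caches[[nm]] <- list(up_in = if (train) up_in, block = o$cache,
                         split = dim(skips[[l]])[3])
    h <- o$y
  }
  y <- conv_fw(gen$layers$final, h)
  caches$final_in <- if (train) h
  list(y = y, gen = gen, cache = if (train) caches)
}

# Concatenate two (H, W, C, N) arrays along the channel axis.
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (any(da[c(1, 2, 4)] != db[c(1, 2, 4)]))
    abort("cannot concatenate: spatial/batch dims differ")
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Reverse-mode pass; returns flat named gradients for every trainable array.
generator_backward <- function(gen, cache, dy) {
  L <- gen$config$levels
  flat <- list()
  g <- conv_bw(gen$layers$final, cache$final_in, dy, need_dx = TRUE)
  flat[["final.w"]] <- g$dw; flat[["final.b"]] <- g$db
  dh <- g$dx
  dskip <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    nm <- paste0("u", l)
    blk <- gen$layers[[nm]]
    bb <- block_bw(blk[c("conv1", "bn1", "conv2", "bn2")],
                   cache[[nm]]$block, dh, need_dx = TRUE)
    for (k in names(fg <- flatten_grads(bb$grads)))
      flat[[paste0(nm, ".", k)]] <- fg[[k]]
    ns <- cache[[nm]]$split
    dcat <- bb$dx
    dskip[[l]] <- dcat[, , seq_len(ns), , drop = FALSE]
    du <- dcat[, , ns + seq_len(dim(dcat)[3] - ns), , drop = FALSE]
    ub <- upconv_bw(blk$up, cache[[nm]]$up_in, du, need_dx = TRUE)
    flat[[paste0(nm, ".up.w")]] <- ub$dw
    flat[[paste0(nm, ".up.b")]] <- ub$db
    dh <- ub$dx
  }
  for (l in rev(seq_len(L))) {
    nm <- paste0("d", l)
    if (l < L) {
      pc <- cache[[paste0("p", l)]]
      dh <- cpp_maxpool2_backward(dh, pc$idx, as.integer(pc$in_dim))
      dh <- dh + dskip[[l]]
    }
    bb <- block_bw(gen$layers[[nm]], cache[[nm]], dh, need_dx = (l > 1))
    for (k in names(fg <- flatten_grads(bb$grads)))
      flat[[paste0(nm, ".", k)]] <- fg[[k]]
    dh <- bb$dx
  }
  flat
}

#' Predict fluorescent channels for a brightfield stack
#'
#' Runs the generator in evaluation mode (batch-norm uses running statistics).
#'
#' @param gen A `bp_generator`.
#' @param x `(H, W, 3)` brightfield stack or `(H, W, 3, N)` batch; H and W
#'   must be divisible by `2^(levels - 1)`.
#' @return `(H, W, 5)` array (or `(H, W, 5, N)` for a batch input).
#' @export
generator_predict <- function(gen, x) {
  single <- length(dim(x)) == 3
  y <- generator_forward(gen, x, train = FALSE)$y
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' Critic (patch discriminator) configuration
#'
#' The critic scores concatenated (brightfield, fluorescent) 8-channel stacks
#' with three kernel-4, stride-2, pad-1 convolutions (filters doubling up to
#' `final_filters`), LeakyReLU(0.2) activations and no normalization layers
#' (standard practice under a gradient penalty), followed by a 1x1
#' convolution to a single-channel spatial score map. The scalar critic score
#' of an input is the mean of its score map.
#'
#' @param in_channels Input channels (3 brightfield + 5 fluorescent).
#' @param n_layers Number of stride-2 convolution layers.
#' @param final_filters Filters in the last stride-2 layer.
#' @return A `bp_critic_config` list.
#' @export
critic_config <- function(in_channels = 8L, n_layers = 3L,
                          final_filters = 64L) {
  structure(list(in_channels = as.integer(in_channels),
                 n_layers = as.integer(n_layers),
                 final_filters = as.integer(final_filters),
                 filters = as.integer(final_filters / 2^((n_layers - 1):0))),
            class = "bp_critic_config")
}

#' Build the patch critic
#'
#' @param config A [critic_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return A `bp_critic`. `critic_score_map()` gives the spatial score map;
#'   `critic_score()` the per-sample scalar scores (map means).
#' @export
build_critic <- function(config = critic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layers <- list()
  cin <- config$in_channels
  for (l in seq_len(config$n_layers)) {
    layers[[paste0("c", l)]] <- nn_conv(cin, config$filters[l], 4L,
                                        stride = 2L, pad = 1L)
    cin <- config$filters[l]
  }
  layers$proj <- nn_conv(cin, 1L, 1L, pad = 0L)
  structure(list(config = config, layers = layers), class = "bp_critic")
}

#' @export
print.bp_critic <- function(x, ...) {
  cat(sprintf("<bp_critic> patch critic, %d input channels, layers %s -> 1, %s trainable parameters\n",
              x$config$in_channels, paste(x$config$filters, collapse = "/"),
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

critic_forward <- function(critic, x, keep = FALSE) {
  x <- as_batch(x)
  if (dim(x)[3] != critic$config$in_channels)
    abort(sprintf("critic expects %d input channels, got %d",
                  critic$config$in_channels, dim(x)[3]))
  caches <- list()
  h <- x
  for (l in seq_len(critic$config$n_layers)) {
    nm <- paste0("c", l)
    a <- conv_fw(critic$layers[[nm]], h)
    if (keep) caches[[nm]] <- list(x = h, pre = a)
    h <- lrelu_fw(a)
  }
  if (keep) caches$proj_in <- h
  map <- conv_fw(critic$layers$proj, h)
  list(map = map, cache = if (keep) caches)
}

# Backward through the critic. `dmap` seeds the score-map gradient. Returns
# parameter gradients (flat) and/or the gradient with respect to the input.
critic_backward <- function(critic, cache, dmap, need_dx = TRUE,
                            need_dpar = TRUE) {
  flat <- list()
  g <- conv_bw(critic$layers$proj, cache$proj_in, dmap, need_dx = TRUE)
  if (need_dpar) { flat[["proj.w"]] <- g$dw; flat[["proj.b"]] <- g$db }
  dh <- g$dx
  for (l in rev(seq_len(critic$config$n_layers))) {
    nm <- paste0("c", l)
    dh <- dh * (0.2 + 0.8 * (cache[[nm]]$pre >= 0))
    dim(dh) <- dim(cache[[nm]]$pre)
    g <- conv_bw(critic$layers[[nm]], cache[[nm]]$x, dh,
                 need_dx = (l > 1 || need_dx))
    if (need_dpar) {
      flat[[paste0(nm, ".w")]] <- g$dw
      flat[[paste0(nm, ".b")]] <- g$db
    }
    dh <- g$dx
  }
  list(grads = flat, dx = if (need_dx) dh)
}

#' Critic score map and scalar scores
#'
#' @param critic A `bp_critic`.
#' @param brightfield `(H, W, 3[, N])` brightfield stack.
#' @param fluorescent `(H, W, 5[, N])` real or generated fluorescent stack.
#' @return `critic_score_map()`: the `(H', W', 1, N)` spatial map of patch
#'   scores; `critic_score()`: numeric vector of per-sample map means.
#' @export
critic_score_map <- function(critic, brightfield, fluorescent) {
  x <- abind4(as_batch(brightfield), as_batch(fluorescent))
  critic_forward(critic, x)$map
}

#' @rdname critic_score_map
#' @export
critic_score <- function(critic, brightfield, fluorescent) {
  m <- critic_score_map(critic, brightfield, fluorescent)
  d <- dim(m)
  colMeans(matrix(m, d[1] * d[2] * d[3], d[4]))
}

#' Count trainable parameters
#'
#' Sums the lengths of every learnable array (convolution weights and biases,
#' batch-norm scale and shift); running statistics are not trainable and are
#' excluded.
#'
#' @param network A `bp_generator` or `bp_critic`.
#' @return Integer-valued count.
#' @examples
#' count_trainable_parameters(
#'   build_generator(generator_config(levels = 2, base_filters = 4), seed = 1))
#' @export
count_trainable_parameters <- function(network) {
  sum(vapply(flatten_params(network$layers), length, numeric(1)))
}
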