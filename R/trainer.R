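#' Training configuration for the two regimes
#'
#' Holds every schedule and optimizer setting of the two training phases: the
#' pure-L1 U-Net phase (batch 10, 50 epochs, Adam lr 2e-4 with weight decay
#' 2e-4) and the cWGAN-GP phase that continues from it (batch 4, 28 epochs,
#' Adam lr 2e-4 with betas (0, 0.9) for both players, critic weight decay
#' 1e-3, five critic updates per generator update, L1 weight 100, gradient
#' penalty weight 10, adversarial weight 1/epoch). No data augmentation is
#' applied anywhere; training inputs are random aligned crops of
#' `patch_size`.
#'
#' @param patch_size Training crop side in pixels; must be divisible by the
#'   generator's pooling stride `2^(levels - 1)`.
#' @param unet_batch,unet_epochs Batch size and epochs of the L1 phase.
#' @param gan_batch,gan_epochs Batch size and epochs of the cWGAN-GP phase.
#' @param critic_steps_per_generator_step Critic updates per generator update.
#' @param unet_lr,unet_weight_decay,unet_betas L1-phase Adam settings.
#' @param gan_lr,gan_betas Generator Adam settings in the GAN phase.
#' @param critic_lr,critic_betas,critic_weight_decay Critic Adam settings.
#' @param weights A [loss_weights()].
#' @param val_fraction Fraction of fields held out for per-epoch validation.
#' @param seed Master seed for splits, batching, crops and initialization.
#' @return A `bp_training_config` list.
#' @export
training_config <- function(patch_size = 256L,
                            unet_batch = 10L, unet_epochs = 50L,
                            gan_batch = 4L, gan_epochs = 28L,
                            critic_steps_per_generator_step = 5L,
                            unet_lr = 2e-4, unet_weight_decay = 2e-4,
                            unet_betas = c(0.9, 0.999),
                            gan_lr = 2e-4, gan_betas = c(0, 0.9),
                            critic_lr = 2e-4, critic_betas = c(0, 0.9),
                            critic_weight_decay = 1e-3,
                            weights = loss_weights(),
                            val_fraction = 0.1,
                            seed = 1L) {
  counts <- c(patch_size, unet_batch, gan_batch,
              critic_steps_per_generator_step)
  if (any(counts < 1)) abort("training_config: all counts must be positive")
  if (unet_epochs < 0 || gan_epochs < 0)
    abort("training_config: epochs must be >= 0")
  structure(list(patch_size = as.integer(patch_size),
                 unet_batch = as.integer(unet_batch),
                 unet_epochs = as.integer(unet_epochs),
                 gan_batch = as.integer(gan_batch),
                 gan_epochs = as.integer(gan_epochs),
                 critic_steps_per_generator_step =
                   as.integer(critic_steps_per_generator_step),
                 unet_lr = unet_lr, unet_weight_decay = unet_weight_decay,
                 unet_betas = unet_betas,
                 gan_lr = gan_lr, gan_betas = gan_betas,
                 critic_lr = critic_lr, critic_betas = critic_betas,
                 critic_weight_decay = critic_weight_decay,
                 weights = weights, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "bp_training_config")
}

#' Iterations implied by a dataset size, batch size and epoch count
#'
#' One epoch visits every training field once in shuffled order, so an epoch
#' has `ceiling(n_train / batch)` iterations (the final short batch is used,
#' not dropped). 3000 fields give 15,000 iterations at batch 10 over 50
#' epochs and 21,000 at batch 4 over 28 epochs.
#'
#' @param n_train Number of training fields.
#' @param batch Batch size.
#' @param epochs Number of epochs.
#' @return Total iteration count.
#' @export
training_iterations <- function(n_train, batch, epochs) {
  epochs * ceiling(n_train / batch)
}

#' Sample an aligned random training crop
#'
#' Crops the same `patch_size` window from the brightfield and fluorescent
#' stacks of a field; the crop origin is uniform over all valid positions.
#'
#' @param field A paired field (see [generate_field()]).
#' @param patch_size Crop side in pixels.
#' @return List with `brightfield` `(patch, patch, 3)` and `fluorescent`
#'   `(patch, patch, 5)` crops.
#' @export
sample_training_patch <- function(field, patch_size = 256L) {
  d <- dim(field$brightfield)
  if (d[1] < patch_size || d[2] < patch_size)
    abort(sprintf("field (%dx%d) smaller than patch size %d",
                  d[1], d[2], patch_size))
  r0 <- if (d[1] == patch_size) 0L else sample.int(d[1] - patch_size + 1L, 1L) - 1L
  c0 <- if (d[2] == patch_size) 0L else sample.int(d[2] - patch_size + 1L, 1L) - 1L
  ri <- r0 + seq_len(patch_size)
  ci <- c0 + seq_len(patch_size)
  list(brightfield = field$brightfield[ri, ci, , drop = FALSE],
       fluorescent = field$fluorescent[ri, ci, , drop = FALSE],
       origin = c(row = r0, col = c0))
}

# Stack per-field crops into (H, W, C, N) batch arrays.
make_batch <- function(fields, idx, patch_size) {
  n <- length(idx)
  p1 <- sample_training_patch(fields[[idx[1]]], patch_size)
  xb <- array(0, c(dim(p1$brightfield)[1:2], dim(p1$brightfield)[3], n))
  yb <- array(0, c(dim(p1$fluorescent)[1:2], dim(p1$fluorescent)[3], n))
  xb[, , , 1] <- p1$brightfield
  yb[, , , 1] <- p1$fluorescent
  if (n > 1) for (j in 2:n) {
    pj <- sample_training_patch(fields[[idx[j]]], patch_size)
    xb[, , , j] <- pj$brightfield
    yb[, , , j] <- pj$fluorescent
  }
  list(x = xb, y = yb)
}

# Accept a list of paired fields or a manifest tibble (rows loaded on demand).
resolve_fields <- function(dataset) {
  if (is.data.frame(dataset)) {
    dataset <- lapply(seq_len(nrow(dataset)), function(i)
      load_field(dataset[i, ]))
  }
  if (!length(dataset)) abort("empty training dataset")
  dataset
}

train_val_split <- function(n, val_fraction) {
  n_val <- max(if (val_fraction > 0) 1L else 0L, floor(n * val_fraction))
  if (n_val >= n) abort("validation split leaves no training fields")
  val <- if (n_val > 0) sample.int(n, n_val) else integer()
  list(train = setdiff(seq_len(n), val), val = val)
}

# Per-epoch validation: eval-mode forward on whole validation fields,
# per-channel Pearson correlation averaged over fields, plus mean L1.
validate_generator <- function(gen, fields) {
  ch <- cp_channels()
  pccs <- matrix(NA_real_, length(fields), length(ch))
  l1s <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    pred <- generator_predict(gen, f$brightfield)
    l1s[i] <- l1_loss(f$fluorescent, pred)
    for (c in seq_along(ch))
      pccs[i, c] <- pcc_safe(f$fluorescent[, , c], pred[, , c])
  }
  m <- colMeans(pccs, na.rm = TRUE)
  out <- c(list(val_l1 = mean(l1s)),
           setNames(as.list(m), paste0("pcc_", ch)),
           list(pcc_mean = mean(m)))
  as_tibble(out)
}

#' Train the U-Net under the L1 objective
#'
#' Minimizes the mean absolute error between predicted and real fluorescent
#' stacks over random aligned crops, with Adam and the configured weight
#' decay. Per-epoch validation metrics (per-channel PCC and L1 on held-out
#' fields) are logged so the best epoch can be selected afterwards.
#'
#' @param dataset List of paired fields (already preprocessed) or a manifest
#'   data frame whose rows [load_field()] can read.
#' @param config A [training_config()].
#' @param generator_config A [generator_config()] for the network to train.
#' @param init Optional `bp_generator` to continue from (fresh otherwise).
#' @param verbose Print a line per epoch.
#' @return A `bp_checkpoint`: the trained generator (final and best-epoch
#'   weights), the configs, and the per-epoch metric `history` tibble.
#' @export
train_unet <- function(dataset, config = training_config(),
                       generator_config = brightpaint::generator_config(),
                       init = NULL, verbose = FALSE) {
  set.seed(config$seed)
  fields <- resolve_fields(dataset)
  check_patch_vs_levels(config$patch_size, generator_config)
  split <- train_val_split(length(fields), config$val_fraction)
  gen <- init %||% build_generator(generator_config)
  opt <- adam_init(flatten_params(gen$layers))
  history <- NULL
  best <- list(pcc = -Inf, gen = gen, epoch = 0L)

  for (epoch in seq_len(config$unet_epochs)) {
    order <- sample(split$train)
    batches <- split(order, ceiling(seq_along(order) / config$unet_batch))
    tr_l1 <- numeric(length(batches))
    for (b in seq_along(batches)) {
      bt <- make_batch(fields, batches[[b]], config$patch_size)
      fw <- generator_forward(gen, bt$x, train = TRUE)
      gen <- fw$gen
      tr_l1[b] <- l1_loss(bt$y, fw$y)
      if (!is.finite(tr_l1[b]))
        abort(sprintf("training diverged (non-finite L1) at epoch %d", epoch))
      dy <- sign(fw$y - bt$y) / length(bt$y)
      grads <- generator_backward(gen, fw$cache, dy)
      st <- adam_step(flatten_params(gen$layers), grads, opt,
                      lr = config$unet_lr, beta1 = config$unet_betas[1],
                      beta2 = config$unet_betas[2],
                      weight_decay = config$unet_weight_decay)
      gen$layers <- assign_params(gen$layers, st$params)
      opt <- st$state
    }
    val <- validate_generator(gen, fields[split$val])
    history <- dplyr::bind_rows(history, dplyr::bind_cols(
      tibble(epoch = epoch, train_l1 = mean(tr_l1)), val))
    if (is.finite(val$pcc_mean) && val$pcc_mean > best$pcc)
      best <- list(pcc = val$pcc_mean, gen = gen, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %d: train L1 %.4f, val L1 %.4f, val PCC %.3f",
                      epoch, mean(tr_l1), val$val_l1, val$pcc_mean))
  }
  new_checkpoint(gen, best, history, config, generator_config, phase = "l1")
}

check_patch_vs_levels <- function(patch_size, gcfg) {
  s <- 2L^(gcfg$levels - 1L)
  if (patch_size %% s != 0)
    abort(sprintf("patch_size %d must be divisible by 2^(levels-1) = %d",
                  patch_size, s))
}

new_checkpoint <- function(gen, best, history, config, generator_config,
                           phase, critic = NULL, counters = NULL) {
  structure(list(generator = gen,
                 best_generator = if (best$epoch > 0) best$gen,
                 best_epoch = if (!is.null(history) && nrow(history))
                   select_best_epoch(history) else 0L,
                 history = history, config = config,
                 generator_config = generator_config,
                 critic = critic, counters = counters, phase = phase),
            class = "bp_checkpoint")
}

#' @export
print.bp_checkpoint <- function(x, ...) {
  cat(sprintf("<bp_checkpoint> phase %s, %d epochs logged, best epoch %s\n",
              x$phase, if (is.null(x$history)) 0L else nrow(x$history),
              x$best_epoch))
  invisible(x)
}

#' Continue training as a conditional WGAN-GP
#'
#' Alternates critic and generator updates at the configured ratio (five
#' critic minimization steps per generator step): the critic minimizes
#' `-(real - fake) + lambda2 * GP` and the generator minimizes
#' `lambda1 * L1 - lambda_e(epoch) * D(x, G(x))` with the adaptive
#' adversarial weight `1/epoch`. By default the generator continues from the
#' L1-trained U-Net checkpoint, matching the two-phase schedule.
#'
#' @param dataset As in [train_unet()].
#' @param config A [training_config()].
#' @param init A `bp_checkpoint` from [train_unet()], a `bp_generator`, or
#'   `NULL` for a cold start.
#' @param generator_config Used only for a cold start.
#' @param verbose Print a line per epoch.
#' @return A `bp_checkpoint` (phase `"cwgan"`) that also carries the critic,
#'   update `counters`, and per-epoch losses and validation metrics.
#' @export
train_cwgan <- function(dataset, config = training_config(), init = NULL,
                        generator_config = brightpaint::generator_config(),
                        verbose = FALSE) {
  set.seed(config$seed + 1L)
  fields <- resolve_fields(dataset)
  gen <- if (inherits(init, "bp_checkpoint")) {
    (init$best_generator %||% init$generator)
  } else if (inherits(init, "bp_generator")) init
  else build_generator(generator_config)
  check_patch_vs_levels(config$patch_size, gen$config)
  critic <- build_critic(critic_config())
  split <- train_val_split(length(fields), config$val_fraction)
  opt_g <- adam_init(flatten_params(gen$layers))
  opt_c <- adam_init(flatten_params(critic$layers))
  w <- config$weights
  history <- NULL
  best <- list(pcc = -Inf, gen = gen, epoch = 0L)
  counters <- c(critic_updates = 0L, generator_updates = 0L)
  ratio <- config$critic_steps_per_generator_step

  for (epoch in seq_len(config$gan_epochs)) {
    le <- lambda_e(epoch)
    order <- sample(split$train)
    batches <- split(order, ceiling(seq_along(order) / config$gan_batch))
    ep_d <- ep_g <- ep_gp <- c()
    for (b in seq_along(batches)) {
      bt <- make_batch(fields, batches[[b]], config$patch_size)
      fake <- generator_forward(gen, bt$x, train = FALSE)$y

      # -- critic step ----------------------------------------------------
      cs <- critic_gp_step(critic, bt$x, bt$y, fake, w)
      st <- adam_step(flatten_params(critic$layers), cs$grads, opt_c,
                      lr = config$critic_lr, beta1 = config$critic_betas[1],
                      beta2 = config$critic_betas[2],
                      weight_decay = config$critic_weight_decay)
      critic$layers <- assign_params(critic$layers, st$params)
      opt_c <- st$state
      counters["critic_updates"] <- counters["critic_updates"] + 1L
      ep_d <- c(ep_d, cs$loss); ep_gp <- c(ep_gp, cs$gp)
      if (!is.finite(cs$loss))
        abort(sprintf("cWGAN training diverged (critic) at epoch %d", epoch))

      # -- generator step every `ratio` batches ---------------------------
      if (counters["critic_updates"] %% ratio == 0) {
        fw <- generator_forward(gen, bt$x, train = TRUE)
        gen <- fw$gen
        l1 <- l1_loss(bt$y, fw$y)
        cfw <- critic_forward(critic, abind4(bt$x, fw$y), keep = TRUE)
        dmap_dim <- dim(cfw$map)
        msz <- prod(dmap_dim[1:3])
        score <- mean(colMeans(matrix(cfw$map, msz, dmap_dim[4])))
        dmap <- array(-le / (msz * dmap_dim[4]), dmap_dim)
        cbw <- critic_backward(critic, cfw$cache, dmap, need_dx = TRUE,
                               need_dpar = FALSE)
        nb <- dim(bt$x)[3]
        dfake <- w$lambda1 * sign(fw$y - bt$y) / length(fw$y) +
          cbw$dx[, , nb + seq_len(dim(fw$y)[3]), , drop = FALSE]
        grads <- generator_backward(gen, fw$cache, dfake)
        st <- adam_step(flatten_params(gen$layers), grads, opt_g,
                        lr = config$gan_lr, beta1 = config$gan_betas[1],
                        beta2 = config$gan_betas[2])
        gen$layers <- assign_params(gen$layers, st$params)
        opt_g <- st$state
        counters["generator_updates"] <- counters["generator_updates"] + 1L
        gl <- generator_objective(l1, score, w, epoch)
        ep_g <- c(ep_g, gl)
        if (!is.finite(gl))
          abort(sprintf("cWGAN training diverged (generator) at epoch %d",
                        epoch))
      }
    }
    val <- validate_generator(gen, fields[split$val])
    history <- dplyr::bind_rows(history, dplyr::bind_cols(
      tibble(epoch = epoch, lambda_e = le,
             critic_loss = mean(ep_d), gp = mean(ep_gp),
             generator_loss = if (length(ep_g)) mean(ep_g) else NA_real_),
      val))
    if (is.finite(val$pcc_mean) && val$pcc_mean > best$pcc)
      best <- list(pcc = val$pcc_mean, gen = gen, epoch = epoch)
    if (verbose)
      message(sprintf(
        "epoch %d: critic %.4f, gp %.4f, gen %.4f, val PCC %.3f",
        epoch, mean(ep_d), mean(ep_gp),
        if (length(ep_g)) mean(ep_g) else NA, val$pcc_mean))
  }
  new_checkpoint(gen, best, history, config, gen$config, phase = "cwgan",
                 critic = critic, counters = counters)
}

# One critic update: Wasserstein surrogate plus gradient penalty. The
# penalty's weight-gradient is obtained from a central finite difference
# along each sample's (unit) input-gradient direction — exact for the
# piecewise-linear critic away from activation kinks.
critic_gp_step <- function(critic, bf, real, fake, w, fd_eps = 1e-3) {
  n <- dim(real)[4]
  fw_r <- critic_forward(critic, abind4(bf, real), keep = TRUE)
  fw_f <- critic_forward(critic, abind4(bf, fake), keep = TRUE)
  md <- dim(fw_r$map)
  msz <- prod(md[1:3])
  s_real <- mean(colMeans(matrix(fw_r$map, msz, md[4])))
  s_fake <- mean(colMeans(matrix(fw_f$map, msz, md[4])))
  g_r <- critic_backward(critic, fw_r$cache,
                         array(-1 / (msz * n), md), need_dx = FALSE)$grads
  g_f <- critic_backward(critic, fw_f$cache,
                         array(+1 / (msz * n), md), need_dx = FALSE)$grads
  grads <- add_flat(g_r, g_f)

  gp <- gp_components(critic, bf, real, fake)
  nz <- gp$norms > 1e-12
  if (any(nz)) {
    u <- gp$grad
    un <- matrix(u, ncol = n)
    un[, nz] <- sweep(un[, nz, drop = FALSE], 2, gp$norms[nz], "/")
    un[, !nz] <- 0
    dim(un) <- dim(u)
    coef <- ifelse(nz, w$lambda2 * 2 * (gp$norms - 1) / n, 0)
    xin <- abind4(bf, gp$xhat)
    shift <- abind4(array(0, dim(bf)), fd_eps * un)
    seed_p <- array(rep(coef / (2 * fd_eps * msz), each = msz), md)
    fw_p <- critic_forward(critic, xin + shift, keep = TRUE)
    g_p <- critic_backward(critic, fw_p$cache, seed_p, need_dx = FALSE)$grads
    fw_m <- critic_forward(critic, xin - shift, keep = TRUE)
    g_m <- critic_backward(critic, fw_m$cache, -seed_p, need_dx = FALSE)$grads
    grads <- add_flat(grads, add_flat(g_p, g_m))
  }
  list(grads = grads,
       loss = critic_objective(s_real, s_fake, gp$value, w),
       gp = gp$value, s_real = s_real, s_fake = s_fake)
}

#' Select the best epoch from a validation-metric history
#'
#' Returns the epoch with the highest mean validation PCC across channels
#' (the headline image metric); ties resolve to the earliest such epoch.
#'
#' @param history A checkpoint `history` tibble (with a `pcc_mean` column) or
#'   a numeric vector of per-epoch mean PCC values.
#' @return 1-based epoch index.
#' @export
select_best_epoch <- function(history) {
  v <- if (is.data.frame(history)) history$pcc_mean else as.numeric(history)
  if (!length(v)) abort("select_best_epoch: empty history")
  v[!is.finite(v)] <- -Inf
  which.max(v)
}
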