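test_that("iteration arithmetic reproduces the published schedules", {
  expect_equal(training_iterations(3000, 10, 50), 15000)
  expect_equal(training_iterations(3000, 4, 28), 21000)
  expect_equal(training_iterations(25, 10, 2), 6)  # short final batch used
})

test_that("training crops are aligned, in-bounds and RNG-driven", {
  f <- list(brightfield = array(seq_len(300 * 280 * 3), c(300, 280, 3)),
            fluorescent = array(seq_len(300 * 280 * 5), c(300, 280, 5)))
  set.seed(1)
  for (i in 1:100) {
    p <- sample_training_patch(f, 256)
    expect_true(p$origin["row"] >= 0 && p$origin["row"] <= 300 - 256)
    expect_true(p$origin["col"] >= 0 && p$origin["col"] <= 280 - 256)
    # alignment: same window cut from both stacks
    expect_equal(p$brightfield[1, 1, 1],
                 f$brightfield[p$origin["row"] + 1, p$origin["col"] + 1, 1])
    expect_equal(p$fluorescent[2, 3, 4],
                 f$fluorescent[p$origin["row"] + 2, p$origin["col"] + 3, 4])
  }
  # exact-size field: the identity crop
  g <- list(brightfield = array(rnorm(64 * 64 * 3), c(64, 64, 3)),
            fluorescent = array(rnorm(64 * 64 * 5), c(64, 64, 5)))
  p <- sample_training_patch(g, 64)
  expect_identical(p$brightfield, g$brightfield)
  # same RNG state, same crop
  set.seed(42); p1 <- sample_training_patch(f, 256)
  set.seed(42); p2 <- sample_training_patch(f, 256)
  expect_identical(p1$origin, p2$origin)
  expect_error(sample_training_patch(g, 256), "smaller")
})

test_that("best-epoch selection maximizes mean PCC with earliest tie-break", {
  expect_equal(select_best_epoch(c(0.1, 0.5, 0.4)), 2)
  expect_equal(select_best_epoch(c(0.3, 0.3)), 1)
  expect_equal(select_best_epoch(c(0.1, 0.2, 0.3)), 3)
  expect_error(select_best_epoch(numeric()), "empty")
})

test_that("zero training epochs return the initial weights unchanged", {
  init <- tiny_generator(seed = 5)
  fields <- tiny_fields(4, size = 64, seed0 = 500)
  cfg <- training_config(patch_size = 32, unet_epochs = 0, seed = 1)
  ck <- train_unet(fields, cfg, init = init)
  expect_identical(ck$generator$layers, init$layers)
  expect_equal(ck$best_epoch, 0)
})

test_that("a short L1 run reduces validation loss below the untrained network", {
  fields <- tiny_fields(12, size = 64, seed0 = 600)
  gcfg <- generator_config(levels = 3, base_filters = 8)
  cfg <- training_config(patch_size = 64, unet_batch = 4, unet_epochs = 3,
                         unet_lr = 2e-3, val_fraction = 0.2, seed = 7)
  # untrained reference on the same validation split
  set.seed(cfg$seed)
  resolved <- brightpaint:::resolve_fields(fields)
  split <- brightpaint:::train_val_split(length(resolved), cfg$val_fraction)
  init <- build_generator(gcfg)
  val0 <- brightpaint:::validate_generator(init, resolved[split$val])
  ck <- train_unet(fields, cfg, gcfg)
  expect_lt(dplyr::last(ck$history$val_l1), val0$val_l1)
  expect_true(all(is.finite(ck$history$train_l1)))
})

test_that("training is reproducible under a fixed seed", {
  fields <- tiny_fields(6, size = 64, seed0 = 700)
  gcfg <- generator_config(levels = 2, base_filters = 4)
  cfg <- training_config(patch_size = 32, unet_batch = 3, unet_epochs = 2,
                         val_fraction = 0.2, seed = 11)
  a <- train_unet(fields, cfg, gcfg)
  b <- train_unet(fields, cfg, gcfg)
  expect_identical(a$history, b$history)
  expect_identical(a$generator$layers, b$generator$layers)
})

test_that("cWGAN training holds the 5:1 critic/generator update ratio", {
  fields <- tiny_fields(21, size = 64, seed0 = 800)
  gcfg <- generator_config(levels = 2, base_filters = 4)
  cfg <- training_config(patch_size = 32, gan_batch = 4, gan_epochs = 2,
                         unet_epochs = 0, val_fraction = 0.05, seed = 13)
  ck <- train_cwgan(fields, cfg, generator_config = gcfg)
  # 20 training fields, batch 4 -> 5 batches/epoch -> 10 critic updates
  expect_equal(unname(ck$counters["critic_updates"]), 10)
  expect_equal(unname(ck$counters["generator_updates"]), 2)
  expect_true(all(is.finite(ck$history$critic_loss)))
  expect_true(all(ck$history$gp >= 0))
  expect_equal(ck$history$lambda_e, c(1, 1 / 2))
})

test_that("adversarial continuation does not catastrophically degrade fidelity", {
  fields <- tiny_fields(12, size = 64, seed0 = 600)
  gcfg <- generator_config(levels = 3, base_filters = 8)
  cfg <- training_config(patch_size = 64, unet_batch = 4, unet_epochs = 3,
                         gan_batch = 4, gan_epochs = 1, unet_lr = 2e-3,
                         val_fraction = 0.2, seed = 7)
  ck_l1 <- train_unet(fields, cfg, gcfg)
  pcc_l1 <- max(ck_l1$history$pcc_mean, na.rm = TRUE)
  ck_gan <- train_cwgan(fields, cfg, init = ck_l1)
  pcc_gan <- max(ck_gan$history$pcc_mean, na.rm = TRUE)
  expect_gte(pcc_gan, pcc_l1 - 0.05)
})
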