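test_that("the same scene spec renders a bit-identical field", {
  a <- generate_field(scene_spec(image_size = 64, seed = 7))
  b <- generate_field(scene_spec(image_size = 64, seed = 7))
  expect_identical(a$brightfield, b$brightfield)
  expect_identical(a$fluorescent, b$fluorescent)
  c <- generate_field(scene_spec(image_size = 64, seed = 8))
  expect_false(identical(a$fluorescent, c$fluorescent))
})

test_that("an empty scene has a background-only DNA channel before noise", {
  f <- generate_field(scene_spec(image_size = 64, n_cells = 0, seed = 1))
  expect_true(all(f$clean_fluorescent[, , "DNA"] == 0))
  expect_equal(max(f$masks$cells), 0)
})

test_that("rendered nucleus count matches the requested cell count", {
  # flood-fill labelling of the thresholded noiseless DNA channel
  f <- generate_field(scene_spec(image_size = 256, n_cells = 20, seed = 3))
  dna <- f$clean_fluorescent[, , "DNA"]
  lab <- EBImage::bwlabel(dna > 0.1 * max(dna))
  expect_equal(max(lab), 20)
})

test_that("invalid scene specs fail with the offending field named", {
  expect_error(scene_spec(image_size = 32), "image_size")
  expect_error(scene_spec(role = "poison"), "role")
  expect_error(scene_spec(noise_sd = -1), "noise_sd")
  expect_error(scene_spec(batch_intensity_shift = c(1, 2)),
               "batch_intensity_shift")
})

test_that("generate_dataset writes a complete, reproducible TIFF tree", {
  plan <- list(scene_spec(image_size = 64, batch_id = "batchA", seed = 1),
               scene_spec(image_size = 64, batch_id = "batchB",
                          batch_intensity_shift = 1.3, seed = 1))
  d1 <- withr::local_tempdir()
  man <- generate_dataset(10, plan, d1, seed = 5)
  expect_equal(nrow(man), 10)
  chan_cols <- paste0("path_", c(bf_planes(), cp_channels()))
  expect_true(all(chan_cols %in% names(man)))   # 8 TIFFs per row
  expect_true(all(file.exists(unlist(man[, chan_cols]))))
  expect_setequal(unique(man$batch), c("batchA", "batchB"))

  d2 <- withr::local_tempdir()
  man2 <- generate_dataset(10, plan, d2, seed = 5)
  md5 <- function(dir) unname(tools::md5sum(sort(list.files(
    dir, pattern = "\\.tif$", full.names = TRUE))))
  expect_identical(md5(d1), md5(d2))            # byte-identical set
})

test_that("batch intensity shift scales fluorescent output by ~30%", {
  mean_int <- function(shift) {
    vals <- vapply(1:20, function(i) {
      f <- generate_field(scene_spec(image_size = 64, noise_sd = 0,
                                     batch_intensity_shift = shift,
                                     seed = 200 + i))
      mean(f$fluorescent)
    }, numeric(1))
    mean(vals)
  }
  ratio <- mean_int(1.3) / mean_int(1)
  expect_equal(ratio, 1.3, tolerance = 0.02)
})

test_that("feature-table plantings are exactly as declared", {
  ft <- generate_feature_table(n_wells = 100, n_features = 60,
                               fraction_nan = 0.1, n_duplicate_pairs = 3,
                               seed = 11)
  pl <- attr(ft, "planted")
  x <- as.matrix(ft[, setdiff(names(ft),
                              c("well_id", "batch", "role", "truth_toxic"))])
  frac_na <- colMeans(is.na(x))
  expect_setequal(names(frac_na)[frac_na > 0.05], pl$nan_features)
  for (j in seq_len(nrow(pl$duplicate_pairs))) {
    r <- cor(x[, pl$duplicate_pairs$a[j]], x[, pl$duplicate_pairs$b[j]],
             use = "complete.obs")
    expect_gt(r, 0.9)
  }
})

test_that("zero effect size leaves toxic wells at the control distribution", {
  ft <- generate_feature_table(n_wells = 200, n_features = 40,
                               effect_size = 0, fraction_nan = 0,
                               n_duplicate_pairs = 0, n_blocklisted = 0,
                               batch_effect = 0, seed = 21)
  pl <- attr(ft, "planted")
  x <- as.matrix(ft[, pl$toxic_features])
  diff <- colMeans(x[ft$truth_toxic, , drop = FALSE]) -
    colMeans(x[!ft$truth_toxic, , drop = FALSE])
  expect_lt(max(abs(diff)), 0.5)
})

test_that("brightfield linearly predicts the DNA channel (learnability)", {
  X <- NULL; Y <- NULL
  for (s in 1:5) {
    fd <- preprocess_field(generate_field(scene_spec(image_size = 128,
                                                     seed = 300 + s)))
    X <- rbind(X, cbind(1, matrix(fd$brightfield, ncol = 3)))
    Y <- c(Y, as.numeric(fd$fluorescent[, , "DNA"]))
  }
  fit <- stats::lm.fit(X, Y)
  expect_gt(cor(X %*% fit$coefficients, Y), 0.5)
})

test_that("phenotype separability grows with the toxic effect size", {
  # feature-space centroid distance between toxic and control wells
  dists <- vapply(c(0, 1, 2, 4), function(es) {
    ft <- generate_feature_table(n_wells = 120, n_features = 30,
                                 effect_size = es, fraction_nan = 0,
                                 n_duplicate_pairs = 0, n_blocklisted = 0,
                                 batch_effect = 0, seed = 31)
    feats <- setdiff(names(ft), c("well_id", "batch", "role", "truth_toxic"))
    centroid_distance(as.matrix(ft[, feats]), ft$truth_toxic)
  }, numeric(1))
  expect_true(all(diff(dists) > 0))
  # and in image space: positive controls enlarge cell area
  areas <- vapply(c(0, 1, 2), function(es) {
    f <- generate_field(scene_spec(image_size = 128,
                                   role = "positive_control",
                                   toxic_effect_size = es, seed = 41))
    mean(f$masks$cells > 0)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})
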