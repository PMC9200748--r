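disc_masks <- function(H = 64, center = c(32, 32), r_cell = 12,
                       r_nuc = 5) {
  g <- expand.grid(r = 1:H, c = 1:H)
  d <- sqrt((g$r - center[1])^2 + (g$c - center[2])^2)
  cells <- matrix(as.integer(d <= r_cell), H, H)
  nuc <- matrix(as.integer(d <= r_nuc), H, H)
  list(nuclei = nuc, cells = cells)
}

test_that("radial ring fractions of a uniform disc follow ring pixel counts", {
  masks <- disc_masks()
  img <- array(1, c(64, 64, 5))
  ft <- extract_standin_features(img, masks)
  # geometry oracle: count pixels per normalized-radius ring
  idx <- which(masks$cells == 1)
  rr <- (idx - 1) %% 64 + 1; cc <- (idx - 1) %/% 64 + 1
  rad <- sqrt((rr - mean(rr))^2 + (cc - mean(cc))^2)
  ring <- pmin(3, floor(rad / max(rad) * 3) + 1)
  for (j in 1:3)
    expect_equal(ft[[paste0("Cells_RadialDistribution_DNA_frac", j)]],
                 sum(ring == j) / length(ring))
})

test_that("intensity features scale linearly and areas count pixels", {
  masks <- disc_masks()
  set.seed(3)
  img <- array(abs(rnorm(64 * 64 * 5)), c(64, 64, 5))
  f1 <- extract_standin_features(img, masks)
  f3 <- extract_standin_features(img * 3, masks)
  expect_equal(f3$Cells_Intensity_DNA_mean, 3 * f1$Cells_Intensity_DNA_mean)
  expect_equal(f3$Cytoplasm_Intensity_Mito_integrated,
               3 * f1$Cytoplasm_Intensity_Mito_integrated)
  expect_equal(f1$Nuclei_AreaShape_none_area, sum(masks$nuclei == 1))
  expect_equal(f1$Cells_AreaShape_none_area, sum(masks$cells == 1))
})

test_that("profiles aggregate by group median with missing-value rules", {
  tb <- tibble::tibble(
    well_id = c("w1", "w1", "w1", "w2", "w2", "w3"),
    role = "treatment",
    Cells_Intensity_DNA_mean = c(1, 2, 9, 1, 3, NA),
    Cells_Intensity_ER_mean = c(NA, NA, NA, 5, NA, 2))
  agg <- aggregate_profiles(tb)
  expect_equal(agg$Cells_Intensity_DNA_mean[agg$well_id == "w1"], 2)
  expect_equal(agg$Cells_Intensity_DNA_mean[agg$well_id == "w2"], 2)
  expect_true(is.na(agg$Cells_Intensity_DNA_mean[agg$well_id == "w3"]))
  expect_true(is.na(agg$Cells_Intensity_ER_mean[agg$well_id == "w1"]))
})

test_that("each selection rule removes exactly its planted violators", {
  ft <- generate_feature_table(n_wells = 100, n_features = 60,
                               fraction_nan = 0.1, n_duplicate_pairs = 3,
                               n_blocklisted = 2, seed = 51)
  pl <- attr(ft, "planted")
  sel <- select_features(ft, blocklist = pl$blocklist_features)
  expect_setequal(sel$dropped$missing, pl$nan_features)
  expect_setequal(sel$dropped$blocklist, pl$blocklist_features)
  # rule 3 removes one member of each planted pair, never both
  expect_length(sel$dropped$correlated, nrow(pl$duplicate_pairs))
  for (j in seq_len(nrow(pl$duplicate_pairs))) {
    pair <- c(pl$duplicate_pairs$a[j], pl$duplicate_pairs$b[j])
    expect_length(intersect(sel$dropped$correlated, pair), 1)
  }
  expect_length(sel$dropped$variable, 0)
  # partition property: survivors + drops = input features
  expect_equal(length(sel$selected) + sum(lengths(sel$dropped)), 60)
})

test_that("rule 1 catches zero-heavy features and rule 4 catches wild DMSO variance", {
  ft <- generate_feature_table(n_wells = 100, n_features = 30,
                               fraction_nan = 0, n_duplicate_pairs = 0,
                               n_blocklisted = 0, seed = 52)
  zf <- "Cells_Intensity_DNA_zeroheavy"
  vf <- "Nuclei_Texture_ER_wild"
  ft[[zf]] <- rnorm(100)
  ft[[zf]][1:6] <- 0                      # 6% zeros > 5%
  ft[[vf]] <- rep(0.5, 100)
  ft[[vf]][which(ft$role == "negative_control")[1]] <- 200  # DMSO SD >> 15
  sel <- select_features(ft)
  expect_true(zf %in% sel$dropped$missing)
  expect_true(vf %in% sel$dropped$variable)
  # 4% zeros is below the threshold
  ft[[zf]][1:6] <- rnorm(6)
  ft[[zf]][1:4] <- 0
  sel2 <- select_features(ft)
  expect_false(zf %in% sel2$dropped$missing)
})

test_that("selection is idempotent and blind to predicted-source values", {
  ft <- generate_feature_table(n_wells = 80, n_features = 40, seed = 53)
  pl <- attr(ft, "planted")
  sel <- select_features(ft, blocklist = pl$blocklist_features)
  again <- select_features(apply_selection(ft, sel),
                           blocklist = pl$blocklist_features)
  expect_setequal(again$selected, sel$selected)
  expect_equal(sum(lengths(again$dropped)), 0)

  # stack a perturbed predicted source on top: identical report
  pred <- ft
  feats <- setdiff(names(ft), c("well_id", "batch", "role", "truth_toxic"))
  pred[, feats] <- pred[, feats] + matrix(rnorm(80 * 40, sd = 10), 80, 40)
  both <- dplyr::bind_rows(dplyr::mutate(ft, source = "ground_truth"),
                           dplyr::mutate(pred, source = "model"))
  sel2 <- select_features(both, blocklist = pl$blocklist_features)
  expect_identical(sel2$selected, sel$selected)
  expect_identical(sel2$dropped, sel$dropped)
})

test_that("grouped correlations honour rank invariance and midranks", {
  ft <- generate_feature_table(n_wells = 50, n_features = 20,
                               fraction_nan = 0, n_duplicate_pairs = 0,
                               n_blocklisted = 0, seed = 54)
  fc <- grouped_feature_correlation(ft, ft)
  expect_true(all(fc$per_feature$rho == 1))
  expect_equal(fc$summary$mean_correlation, 1)
  # strictly monotone transform preserves Spearman exactly
  pred <- ft
  feats <- brightpaint:::feature_columns(ft)
  pred[, feats] <- (ft[, feats])^3
  fc2 <- grouped_feature_correlation(pred, ft)
  expect_true(all(abs(fc2$per_feature$rho - 1) < 1e-12))
  # ties: midrank oracle (rank then Pearson)
  pred2 <- ft
  pred2[[feats[1]]] <- round(ft[[feats[1]]])    # heavy ties
  fc3 <- grouped_feature_correlation(pred2, ft)
  oracle <- cor(rank(pred2[[feats[1]]]), rank(ft[[feats[1]]]))
  expect_equal(fc3$per_feature$rho[fc3$per_feature$feature == feats[1]],
               oracle, tolerance = 1e-12)
  # group means are the feature-count-weighted decomposition of the mean
  g <- fc3$groups
  expect_equal(sum(g$mean_rho * g$n_features) / sum(g$n_features),
               fc3$summary$mean_correlation, tolerance = 1e-12)
  expect_error(grouped_feature_correlation(ft[, -5], ft), "differ")
})

test_that("embeddings give 2-D coordinates separating planted clusters", {
  ft <- generate_feature_table(n_wells = 60, n_features = 20,
                               effect_size = 8, fraction_nan = 0,
                               n_duplicate_pairs = 0, n_blocklisted = 0,
                               batch_effect = 0, seed = 55)
  norm <- normalize_profiles(ft)
  for (method in c("pca", "umap")) {
    emb <- embed_profiles(norm, method = method, n_epochs = 100, seed = 9)
    xy <- cbind(emb$dim1, emb$dim2)
    expect_equal(ncol(xy), 2)
    d_between <- centroid_distance(xy, ft$truth_toxic)
    spread <- max(stats::quantile(sqrt(rowSums(
      sweep(xy[ft$truth_toxic, ], 2,
            colMeans(xy[ft$truth_toxic, ]))^2)), 0.95),
      stats::quantile(sqrt(rowSums(
        sweep(xy[!ft$truth_toxic, ], 2,
              colMeans(xy[!ft$truth_toxic, ]))^2)), 0.95))
    expect_gt(d_between, spread)
  }
})

test_that("duplicated profiles embed to near-coincident points", {
  ft <- generate_feature_table(n_wells = 40, n_features = 15,
                               fraction_nan = 0, n_duplicate_pairs = 0,
                               n_blocklisted = 0, seed = 56)
  dup <- ft[c(1:40, 1), ]
  dup$well_id[41] <- "w_dup"
  emb <- embed_profiles(normalize_profiles(dup), method = "umap",
                        n_epochs = 300, seed = 10)
  xy <- cbind(emb$dim1, emb$dim2)
  d_dup <- sqrt(sum((xy[41, ] - xy[1, ])^2))
  spread <- median(as.matrix(dist(xy))[upper.tri(diag(41))])
  expect_lt(d_dup, spread / 2)
  expect_error(embed_profiles(normalize_profiles(ft[1:10, ]),
                              method = "umap"), "rows")
})
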