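# Shared fixture builders. Everything is generated in code at test time.

tiny_fields <- function(n, size = 64, noise_sd = 0.01, seed0 = 100,
                        role = "treatment") {
  lapply(seq_len(n), function(i)
    preprocess_field(generate_field(scene_spec(
      image_size = size, noise_sd = noise_sd, role = role,
      seed = seed0 + i))))
}

tiny_generator <- function(seed = 1) {
  build_generator(generator_config(levels = 3, base_filters = 8),
                  seed = seed)
}

# Euclidean centroid distance between two row sets of a feature matrix.
centroid_distance <- function(x, mask) {
  a <- colMeans(x[mask, , drop = FALSE], na.rm = TRUE)
  b <- colMeans(x[!mask, , drop = FALSE], na.rm = TRUE)
  sqrt(sum((a - b)^2))
}

# Gaussian two-class profile table with controls, for toxicity tests.
gaussian_profiles <- function(n_per_class = 20, n_features = 10,
                              effect = 5, seed = 1,
                              n_pos_ctrl = 6, n_neg_ctrl = 8) {
  withr_seed <- function(code) code
  set.seed(seed)
  n <- 2 * n_per_class
  toxic <- rep(c(TRUE, FALSE), each = n_per_class)
  m <- matrix(rnorm(n * n_features), n, n_features)
  m[toxic, 1:3] <- m[toxic, 1:3] + effect
  roles <- rep("treatment", n)
  roles[which(toxic)[seq_len(n_pos_ctrl)]] <- "positive_control"
  roles[which(!toxic)[seq_len(n_neg_ctrl)]] <- "negative_control"
  colnames(m) <- make_names_for_profiles(n_features)
  dplyr::bind_cols(
    tibble::tibble(well_id = sprintf("w%03d", 1:n), batch = "batchA",
                   role = roles, truth_toxic = toxic),
    tibble::as_tibble(m))
}

make_names_for_profiles <- function(n) {
  paste0("Cells_Intensity_", rep(cp_channels(), length.out = n),
         "_f", sprintf("%02d", seq_len(n)))
}
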