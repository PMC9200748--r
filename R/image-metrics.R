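#' Paired-image evaluation metrics
#'
#' The five metrics used to score a predicted channel against its ground
#' truth: mean absolute error, mean squared error, Pearson correlation of
#' the flattened pixels, peak signal-to-noise ratio on a shared 8-bit scale,
#' and the structural similarity index. All treat the two images
#' symmetrically (for PSNR this holds because the 8-bit conversion uses one
#' affine map shared by both images).
#'
#' @param a,b Numeric matrices (single channels) of identical shape.
#' @return A scalar.
#' @name image_metrics
NULL

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    abort("image metric: shape mismatch between the two images")
}

#' @rdname image_metrics
#' @export
mae <- function(a, b) {
  check_same_shape(a, b)
  mean(abs(a - b))
}

#' @rdname image_metrics
#' @export
mse <- function(a, b) {
  check_same_shape(a, b)
  mean((a - b)^2)
}

#' @rdname image_metrics
#' @export
pcc <- function(a, b) {
  check_same_shape(a, b)
  if (sd(a) == 0 || sd(b) == 0)
    abort("pcc: undefined for a zero-variance image")
  cor(as.numeric(a), as.numeric(b))
}

# NA instead of an error on degenerate images (used for validation logging).
pcc_safe <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(NA_real_)
  cor(as.numeric(a), as.numeric(b))
}

#' @rdname image_metrics
#' @details
#' `psnr_8bit()` maps both images with a single affine transform from the
#' min/max of their union onto `[0, 255]` (values are kept continuous, not
#' quantized), then returns `10 * log10(255^2 / MSE)`. Identical images give
#' `Inf`.
#' @export
psnr_8bit <- function(a, b) {
  check_same_shape(a, b)
  lo <- min(a, b); hi <- max(a, b)
  if (hi == lo) return(Inf)
  a8 <- (a - lo) / (hi - lo) * 255
  b8 <- (b - lo) / (hi - lo) * 255
  m <- mean((a8 - b8)^2)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

#' @rdname image_metrics
#' @param win_size Side of the square (uniform) local window, default 7.
#' @param K1,K2 Stabilizing constants entering `C1 = (K1 * L)^2` and
#'   `C2 = (K2 * L)^2`.
#' @param data_range Dynamic range `L`; defaults to the range of the two
#'   images' union.
#' @details
#' `ssim()` evaluates local means, variances and covariance on every fully
#' interior `win_size x win_size` window (uniform weighting, unbiased
#' variance normalization), forms the standard two-term SSIM map and returns
#' its mean.
#' @export
ssim <- function(a, b, win_size = 7L, K1 = 0.01, K2 = 0.03,
                 data_range = NULL) {
  check_same_shape(a, b)
  if (nrow(a) < win_size || ncol(a) < win_size)
    abort(sprintf("ssim: image smaller than the %dx%d window", win_size,
                  win_size))
  L <- data_range %||% (max(a, b) - min(a, b))
  if (L == 0) L <- 1   # identical constants: SSIM is 1 regardless of L
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  np <- win_size^2
  mu_a <- box_mean(a, win_size)
  mu_b <- box_mean(b, win_size)
  # unbiased local (co)variances, matching the reference implementation
  unb <- np / (np - 1)
  va <- (box_mean(a * a, win_size) - mu_a^2) * unb
  vb <- (box_mean(b * b, win_size) - mu_b^2) * unb
  vab <- (box_mean(a * b, win_size) - mu_a * mu_b) * unb
  s <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

# Mean over every fully interior k x k window, via an integral image.
box_mean <- function(x, k) {
  s <- rbind(0, apply(x, 2, cumsum))
  s <- cbind(0, t(apply(s, 1, cumsum)))
  n <- nrow(x); m <- ncol(x)
  i <- 1:(n - k + 1); j <- 1:(m - k + 1)
  (s[i + k, j + k, drop = FALSE] - s[i, j + k, drop = FALSE] -
     s[i + k, j, drop = FALSE] + s[i, j, drop = FALSE]) / (k * k)
}

#' Evaluate a predicted field against its ground truth
#'
#' Computes all five image metrics per fluorescent channel plus the
#' cross-channel means, in the canonical channel order (DNA, ER, RNA, AGP,
#' Mito).
#'
#' @param prediction,truth `(H, W, 5)` arrays.
#' @param channels Channel names (fixed canonical order by default).
#' @return A `bp_metric_report`: a tibble with one row per channel and
#'   columns `mae`, `mse`, `ssim`, `psnr`, `pcc`; the attribute `"means"`
#'   holds the per-metric cross-channel means (also via [glance()]).
#' @export
evaluate_field <- function(prediction, truth, channels = cp_channels()) {
  if (!identical(dim(prediction), dim(truth)))
    abort("evaluate_field: prediction and truth shapes differ")
  rows <- purrr::map_dfr(seq_along(channels), function(c) {
    p <- prediction[, , c]; t <- truth[, , c]
    tibble(channel = channels[c],
           mae = mae(t, p), mse = mse(t, p), ssim = ssim(t, p),
           psnr = psnr_8bit(t, p), pcc = pcc(t, p))
  })
  means <- colMeans(rows[, c("mae", "mse", "ssim", "psnr", "pcc")])
  structure(rows, class = c("bp_metric_report", class(rows)), means = means)
}

#' Aggregate metric reports over a set of fields
#'
#' @param reports List of `bp_metric_report` objects (one per field).
#' @return Tibble with per-channel, per-metric mean and standard deviation
#'   across fields (the `mean +/- sd` presentation used for test sets).
#' @export
summarize_metric_reports <- function(reports) {
  long <- purrr::imap_dfr(reports, function(r, i)
    dplyr::mutate(tidy(r), field = i))
  long |>
    dplyr::group_by(.data$channel, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
}
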