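test_that("MAE/MSE match their definitions and a loop oracle", {
  a <- matrix(rnorm(400), 20, 20)
  b <- matrix(rnorm(400), 20, 20)
  expect_equal(mae(a, a), 0)
  expect_equal(mse(a, a), 0)
  expect_equal(mae(a, a + 2), 2)
  expect_equal(mse(a, a + 2), 4)
  s_abs <- 0; s_sq <- 0
  for (i in 1:20) for (j in 1:20) {
    s_abs <- s_abs + abs(a[i, j] - b[i, j])
    s_sq <- s_sq + (a[i, j] - b[i, j])^2
  }
  expect_equal(mae(a, b), s_abs / 400)
  expect_equal(mse(a, b), s_sq / 400)
  expect_error(mae(a, matrix(0, 5, 5)), "shape")
})

test_that("PCC is affine-invariant and errors on zero variance", {
  a <- matrix(rnorm(256), 16, 16)
  expect_equal(pcc(a, 2 * a + 3), 1)
  expect_equal(pcc(a, -a), -1)
  b <- matrix(rnorm(256), 16, 16)
  # two-pass textbook formula
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pcc(a, b), num / den)
  expect_error(pcc(matrix(1, 4, 4), matrix(rnorm(16), 4, 4)), "variance")
})

test_that("PSNR uses the shared 8-bit map and closed forms", {
  a <- matrix(seq(0, 254, length.out = 225), 15, 15)
  b <- a + 1
  # union range [0, 255] -> identity map -> unit difference everywhere
  expect_equal(psnr_8bit(a, b), 20 * log10(255), tolerance = 1e-12)
  expect_identical(psnr_8bit(a, a), Inf)
  # symmetry through the shared map
  x <- matrix(rnorm(100), 10, 10); y <- matrix(rnorm(100), 10, 10)
  expect_equal(psnr_8bit(x, y), psnr_8bit(y, x))
  # oracle from mse after the same conversion
  lo <- min(x, y); hi <- max(x, y)
  m8 <- mse((x - lo) / (hi - lo) * 255, (y - lo) / (hi - lo) * 255)
  expect_equal(psnr_8bit(x, y), 10 * log10(255^2 / m8))
})

test_that("SSIM matches identity, the luminance closed form, and a window oracle", {
  a <- matrix(rnorm(256), 16, 16)
  expect_equal(ssim(a, a), 1)
  # constants differ: only the luminance term acts
  c1 <- matrix(2, 16, 16); c2 <- matrix(5, 16, 16)
  L <- 10; C1 <- (0.01 * L)^2
  expect_equal(ssim(c1, c2, data_range = L),
               (2 * 2 * 5 + C1) / (2^2 + 5^2 + C1))
  expect_lt(ssim(c1, c2, data_range = L), 1)
  # brute-force windowed oracle on a small pair
  b <- a + 0.3 * matrix(rnorm(256), 16, 16)
  L <- max(a, b) - min(a, b)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  vals <- c()
  for (i in 1:(16 - 6)) for (j in 1:(16 - 6)) {
    wa <- a[i:(i + 6), j:(j + 6)]; wb <- b[i:(i + 6), j:(j + 6)]
    va <- var(as.numeric(wa)); vb <- var(as.numeric(wb))
    vab <- cov(as.numeric(wa), as.numeric(wb))
    vals <- c(vals, (2 * mean(wa) * mean(wb) + C1) * (2 * vab + C2) /
                ((mean(wa)^2 + mean(wb)^2 + C1) * (va + vb + C2)))
  }
  expect_equal(ssim(a, b), mean(vals), tolerance = 1e-10)
  expect_error(ssim(matrix(0, 5, 5), matrix(0, 5, 5)), "window")
})

test_that("SSIM agrees with the scikit-image reference implementation", {
  set.seed(8)
  a <- matrix(rnorm(64 * 64), 64, 64)
  b <- a + 0.5 * matrix(rnorm(64 * 64), 64, 64)
  L <- max(a, b) - min(a, b)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  fo <- tempfile(fileext = ".txt")
  write.table(a, fa, row.names = FALSE, col.names = FALSE, sep = ",")
  write.table(b, fb, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(paste0(
    "import numpy as np; from skimage.metrics import structural_similarity as s; ",
    "a = np.loadtxt('%s', delimiter=','); b = np.loadtxt('%s', delimiter=','); ",
    "open('%s', 'w').write('%%.17g' %% s(a, b, win_size=7, ",
    "gaussian_weights=False, data_range=%.17g))"), fa, fb, fo, L)
  status <- system2("python", c("-c", shQuote(code)))
  expect_equal(status, 0)
  ref <- as.numeric(readLines(fo, warn = FALSE))
  expect_equal(ssim(a, b), ref, tolerance = 1e-6)
})

test_that("evaluate_field reports all metrics per channel in canonical order", {
  set.seed(9)
  truth <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  rep0 <- evaluate_field(truth, truth)
  expect_equal(rep0$channel, cp_channels())
  expect_true(all(rep0$mae == 0) && all(rep0$mse == 0))
  expect_true(all(rep0$ssim == 1) && all(rep0$pcc == 1))
  expect_true(all(is.infinite(rep0$psnr)))

  pred <- truth + 0.2 * array(rnorm(32 * 32 * 5), c(32, 32, 5))
  rep1 <- evaluate_field(pred, truth)
  means <- attr(rep1, "means")
  expect_equal(unname(means["pcc"]), mean(rep1$pcc))
  expect_equal(unname(means["mae"]), mean(rep1$mae))
  g <- glance(rep1)
  expect_equal(g$pcc, mean(rep1$pcc))
  expect_equal(nrow(tidy(rep1)), 25)
})

test_that("metric reports aggregate to mean and SD across fields", {
  set.seed(10)
  reps <- lapply(1:3, function(i) {
    t <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
    evaluate_field(t + 0.3 * array(rnorm(length(t)), dim(t)), t)
  })
  sm <- summarize_metric_reports(reps)
  expect_equal(nrow(sm), 25)
  one <- sm[sm$channel == "DNA" & sm$metric == "pcc", ]
  vals <- vapply(reps, function(r) r$pcc[r$channel == "DNA"], numeric(1))
  expect_equal(one$mean, mean(vals))
  expect_equal(one$sd, sd(vals))
})
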