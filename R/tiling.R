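#' Plan the sliding-window tiling of a field
#'
#' Inference runs on `patch x patch` windows laid out on a `stride` grid.
#' Origins advance by `stride` along each axis; when the grid does not land
#' exactly on the far edge, a final origin is clamped to `H - patch` (resp.
#' `W - patch`) so every pixel is covered and all patches lie fully inside
#' the image. With the default half-patch stride interior pixels are covered
#' by exactly four patches.
#'
#' @param H,W Image size in pixels (both `>= patch`).
#' @param patch Patch side (default 256).
#' @param stride Grid stride (default 128).
#' @return A `bp_tiling_plan`: list with `origins` (tibble of 0-based `row`,
#'   `col` patch offsets), the integer `coverage` map (per-pixel overlap
#'   counts), and the geometry parameters.
#' @examples
#' plan <- plan_tiles(998, 998)
#' max(unique(plan$origins$row))  # 742, the clamped final origin
#' @export
plan_tiles <- function(H, W, patch = 256L, stride = 128L) {
  if (H < patch || W < patch)
    abort(sprintf("image %dx%d smaller than patch %d", H, W, patch))
  axis_origins <- function(n) {
    o <- seq.int(0L, n - patch, by = stride)
    unique(c(o, n - patch))
  }
  ro <- axis_origins(H)
  co <- axis_origins(W)
  origins <- tidyr::expand_grid(row = ro, col = co)
  coverage <- matrix(0L, H, W)
  for (i in seq_len(nrow(origins))) {
    ri <- origins$row[i] + seq_len(patch)
    ci <- origins$col[i] + seq_len(patch)
    coverage[ri, ci] <- coverage[ri, ci] + 1L
  }
  structure(list(H = as.integer(H), W = as.integer(W),
                 patch = as.integer(patch), stride = as.integer(stride),
                 origins = origins, coverage = coverage),
            class = "bp_tiling_plan")
}

#' @export
print.bp_tiling_plan <- function(x, ...) {
  cat(sprintf("<bp_tiling_plan> %dx%d image, %d patches of %d (stride %d), coverage %d..%d\n",
              x$H, x$W, nrow(x$origins), x$patch, x$stride,
              min(x$coverage), max(x$coverage)))
  invisible(x)
}

#' Median-stitch per-patch predictions into a full image
#'
#' Every output pixel is the median of the values predicted for it by all
#' patches that cover it (four in the interior at half-patch stride; fewer
#' near edges and corners). An even overlap count uses the mean of the two
#' middle order statistics. Stitching patches cut from a single image
#' reproduces that image exactly, and the result does not depend on the
#' order of the origins.
#'
#' @param patch_predictions List of `(patch, patch, C)` arrays, one per row
#'   of `plan$origins` (same order).
#' @param plan A [plan_tiles()] result.
#' @return `(H, W, C)` stitched array.
#' @export
stitch_median <- function(patch_predictions, plan) {
  np <- nrow(plan$origins)
  if (length(patch_predictions) != np)
    abort(sprintf("got %d patch predictions for a plan with %d origins",
                  length(patch_predictions), np))
  d1 <- dim(patch_predictions[[1]])
  C <- if (length(d1) == 2) 1L else d1[3]
  maxcov <- max(plan$coverage)
  out <- array(NA_real_, c(plan$H, plan$W, C))
  for (ch in seq_len(C)) {
    acc <- array(0, c(plan$H, plan$W, maxcov))
    fill <- matrix(0L, plan$H, plan$W)
    for (i in seq_len(np)) {
      ri <- plan$origins$row[i] + seq_len(plan$patch)
      ci <- plan$origins$col[i] + seq_len(plan$patch)
      p <- patch_predictions[[i]]
      pc <- if (length(dim(p)) == 2) p else p[, , ch]
      # each pixel's value goes into its next free accumulator layer
      base <- outer(ri - 1L, (ci - 1L) * plan$H, "+") + 1L
      acc[base + as.numeric(plan$H) * plan$W * fill[ri, ci]] <- pc
      fill[ri, ci] <- fill[ri, ci] + 1L
    }
    out[, , ch] <- cpp_masked_median(acc, fill)
  }
  out
}

#' Tiled inference over a full field
#'
#' Plans the tiling, runs the generator on every patch (in evaluation mode)
#' and median-stitches the per-patch predictions. Deterministic given the
#' generator weights.
#'
#' @param generator A `bp_generator`, or a plain function mapping one
#'   `(patch, patch, 3)` brightfield crop to a `(patch, patch, 5)`
#'   prediction (useful for diagnostics).
#' @param field A paired field whose `brightfield` stack is predicted.
#' @param patch,stride Tiling geometry (defaults 256/128).
#' @param batch_size Patches per forward pass for a network generator.
#' @return `(H, W, 5)` predicted fluorescent stack.
#' @export
predict_field <- function(generator, field, patch = 256L, stride = 128L,
                          batch_size = 4L) {
  bf <- field$brightfield
  d <- dim(bf)
  plan <- plan_tiles(d[1], d[2], patch, stride)
  crops <- lapply(seq_len(nrow(plan$origins)), function(i) {
    bf[plan$origins$row[i] + seq_len(patch),
       plan$origins$col[i] + seq_len(patch), , drop = FALSE]
  })
  preds <- if (is.function(generator)) {
    lapply(crops, generator)
  } else {
    out <- vector("list", length(crops))
    for (s in split(seq_along(crops), ceiling(seq_along(crops) / batch_size))) {
      xb <- array(0, c(patch, patch, d[3], length(s)))
      for (j in seq_along(s)) xb[, , , j] <- crops[[s[j]]]
      yb <- generator_forward(generator, xb, train = FALSE)$y
      for (j in seq_along(s)) out[[s[j]]] <- yb[, , , j]
    }
    out
  }
  stitch_median(preds, plan)
}
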