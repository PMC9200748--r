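# Image and manifest I/O. Raw images travel as one 16-bit single-channel
# TIFF per channel; synthetic intensities use ~[0, 20000] of the 16-bit
# range, mimicking real microscopy headroom. Signed (z-normalized)
# predictions are written as float TIFFs after an affine map to [0, 1],
# recorded in a JSON sidecar.

field_channel_names <- function() c(bf_planes(), cp_channels())

#' Write a paired field as per-channel 16-bit TIFFs
#'
#' @param field A `bp_field` with a `field_id` in its metadata.
#' @param dir Output directory.
#' @param intensity_scale Scene-to-integer scale (default 16000, leaving
#'   16-bit headroom).
#' @return Named character vector of written paths (`path_<channel>` for the
#'   eight channels plus the two label masks).
#' @export
write_field <- function(field, dir, intensity_scale = 16000) {
  id <- field$metadata$field_id
  if (is.na(id) || is.null(id)) id <- "field"
  wr16 <- function(x, name) {
    p <- file.path(dir, sprintf("%s_%s.tif", id, name))
    v <- pmin(pmax(round(x * intensity_scale), 0), 65535) / 65535
    ok <- tryCatch(tiff::writeTIFF(v, p, bits.per.sample = 16L),
                   error = function(e)
                     abort(sprintf("failed writing '%s': %s", p,
                                   conditionMessage(e))))
    p
  }
  paths <- c()
  for (i in 1:3)
    paths[paste0("path_", bf_planes()[i])] <-
      wr16(field$brightfield[, , i], bf_planes()[i])
  for (i in 1:5)
    paths[paste0("path_", cp_channels()[i])] <-
      wr16(field$fluorescent[, , i], cp_channels()[i])
  if (!is.null(field$masks)) {
    wrlab <- function(m, name) {
      p <- file.path(dir, sprintf("%s_%s.tif", id, name))
      tiff::writeTIFF(m / 65535, p, bits.per.sample = 16L)
      p
    }
    paths["path_mask_nuclei"] <- wrlab(field$masks$nuclei, "mask-nuclei")
    paths["path_mask_cells"] <- wrlab(field$masks$cells, "mask-cells")
  }
  paths
}

#' Load a paired field from a manifest row
#'
#' Reassembles the brightfield and fluorescent stacks (and label masks when
#' present) from the per-channel TIFF paths of one manifest row, restoring
#' raw integer intensities.
#'
#' @param row One-row data frame with `path_<channel>` columns and metadata
#'   columns (`field_id`, `batch`, `well`, `role`).
#' @param intensity_scale Scale used when the field was written; restored
#'   intensities are divided by it so scene units come back.
#' @return A `bp_field`.
#' @export
load_field <- function(row, intensity_scale = 16000) {
  rd <- function(ch) {
    col <- paste0("path_", ch)
    if (!col %in% names(row) || is.na(row[[col]]))
      abort(sprintf("manifest row is missing the %s channel for field %s",
                    ch, row$field_id %||% "?"))
    p <- row[[col]]
    if (!file.exists(p))
      abort(sprintf("missing file for channel %s: '%s'", ch, p))
    round(tiff::readTIFF(p) * 65535) / intensity_scale
  }
  H <- NULL
  bf <- NULL
  for (i in 1:3) {
    m <- rd(bf_planes()[i])
    if (is.null(bf)) bf <- array(0, c(dim(m), 3))
    bf[, , i] <- m
  }
  fl <- array(0, c(dim(bf)[1:2], 5))
  for (i in 1:5) fl[, , i] <- rd(cp_channels()[i])
  masks <- NULL
  if ("path_mask_nuclei" %in% names(row)) {
    masks <- list(
      nuclei = round(tiff::readTIFF(row$path_mask_nuclei) * 65535),
      cells = round(tiff::readTIFF(row$path_mask_cells) * 65535))
    storage.mode(masks$nuclei) <- "integer"
    storage.mode(masks$cells) <- "integer"
  }
  dimnames(fl) <- list(NULL, NULL, cp_channels())
  dimnames(bf) <- list(NULL, NULL, bf_planes())
  structure(list(brightfield = bf, fluorescent = fl, masks = masks,
                 metadata = list(batch_id = row$batch %||% NA,
                                 well_id = row$well %||% NA,
                                 field_id = row$field_id %||% NA,
                                 role = row$role %||% NA)),
            class = "bp_field")
}

#' Save and reload predicted fluorescent stacks
#'
#' Predictions are z-scale (signed) floats, so each channel is affinely
#' mapped to `[0, 1]`, written as a 32-bit float TIFF, and the per-channel
#' affine recorded in a JSON sidecar; `load_prediction()` inverts the map
#' (round-trip error below 1e-6).
#'
#' @param field_id Identifier used in file names.
#' @param channels `(H, W, 5)` predicted stack.
#' @param dir Output directory.
#' @return Named vector of written paths (5 TIFFs + sidecar).
#' @export
save_prediction <- function(field_id, channels, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scales <- list()
  paths <- c()
  for (i in 1:5) {
    ch <- cp_channels()[i]
    x <- channels[, , i]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    p <- file.path(dir, sprintf("%s_pred_%s.tif", field_id, ch))
    tiff::writeTIFF((x - lo) / (hi - lo), p, bits.per.sample = 32L)
    scales[[ch]] <- list(lo = lo, hi = hi)
    paths[paste0("path_pred_", ch)] <- p
  }
  sp <- file.path(dir, sprintf("%s_pred_scale.json", field_id))
  jsonlite::write_json(scales, sp, digits = NA, auto_unbox = FALSE)
  paths["path_pred_scale"] <- sp
  paths
}

#' @rdname save_prediction
#' @export
load_prediction <- function(field_id, dir) {
  scales <- jsonlite::read_json(
    file.path(dir, sprintf("%s_pred_scale.json", field_id)),
    simplifyVector = TRUE)
  out <- NULL
  for (i in 1:5) {
    ch <- cp_channels()[i]
    v <- tiff::readTIFF(file.path(dir, sprintf("%s_pred_%s.tif", field_id, ch)))
    if (is.null(out)) out <- array(0, c(dim(v), 5))
    s <- unlist(scales[[ch]])
    out[, , i] <- v * (s[["hi"]] - s[["lo"]]) + s[["lo"]]
  }
  dimnames(out) <- list(NULL, NULL, cp_channels())
  out
}

#' Preprocess a field: optional bilinear half-downscale, then per-image
#' per-channel standardization
#'
#' Mirrors the acquisition-side pipeline: raw images are bilinearly
#' downscaled by a factor of two when larger than the working size, and
#' every channel of every image is independently constrained to mean 0 and
#' standard deviation 1. Because the normalization is per image, batch-level
#' intensity differences are removed at this stage. Label masks, when
#' present, are downscaled with nearest-neighbour sampling.
#'
#' @param field A `bp_field` with raw intensities.
#' @param working_size Target side in pixels; when set and the field is
#'   larger, one bilinear x0.5 downscale is applied (1996 -> 998 in the
#'   reference pipeline). `NULL` (default) skips downscaling.
#' @param sd_floor Lower bound for the per-channel SD; 0 (default) makes a
#'   constant channel an error.
#' @return The preprocessed `bp_field` (z-scale intensities).
#' @export
preprocess_field <- function(field, working_size = NULL, sd_floor = 0) {
  H <- dim(field$brightfield)[1]
  if (!is.null(working_size) && H > working_size) {
    half <- function(x) EBImage::resize(x, w = dim(x)[1] / 2,
                                        h = dim(x)[2] / 2)
    bf <- array(0, c(H / 2, dim(field$brightfield)[2] / 2, 3))
    for (i in 1:3) bf[, , i] <- half(field$brightfield[, , i])
    fl <- array(0, c(dim(bf)[1:2], 5))
    for (i in 1:5) fl[, , i] <- half(field$fluorescent[, , i])
    field$brightfield <- bf
    field$fluorescent <- fl
    if (!is.null(field$masks))
      field$masks <- lapply(field$masks, function(m) {
        r <- EBImage::resize(m, w = nrow(m) / 2, h = ncol(m) / 2,
                             filter = "none")
        storage.mode(r) <- "integer"
        r
      })
  }
  znorm <- function(x, ch) {
    s <- sd(x)
    if (s < 1e-12) {
      if (sd_floor <= 0)
        abort(sprintf("constant %s channel: zero SD (set sd_floor to allow)",
                      ch))
      s <- sd_floor
    }
    (x - mean(x)) / max(s, sd_floor)
  }
  for (i in 1:3)
    field$brightfield[, , i] <- znorm(field$brightfield[, , i], bf_planes()[i])
  for (i in 1:5)
    field$fluorescent[, , i] <- znorm(field$fluorescent[, , i],
                                      cp_channels()[i])
  field$preprocessed <- TRUE
  field
}

#' Read or write a dataset manifest
#'
#' @param path Manifest TSV path.
#' @return `read_manifest()`: the manifest tibble.
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}
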