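#' Scene specification for one synthetic paired field
#'
#' Describes a field of view for the built-in paired-microscopy emulator:
#' cells are rendered as elliptical nuclei inside larger cytoplasm blobs,
#' the five fluorescent channels are deterministic functions of that scene,
#' and the three brightfield planes are channel mixtures degraded by
#' plane-specific defocus blur. Positive-control scenes show a toxic
#' phenotype: enlarged cells with a suppressed density of mitochondrial
#' puncta, scaled by `toxic_effect_size`.
#'
#' @param image_size Field side in pixels (>= 64).
#' @param n_cells Number of cells; defaults to a density of one cell per
#'   ~1800 px^2. Placement rejects nucleus overlaps, so the count is exact.
#' @param batch_id Batch label.
#' @param batch_intensity_shift Multiplicative intensity factor applied to
#'   the fluorescent channels (length 1 or 5), emulating batch effects.
#' @param role One of `"negative_control"`, `"positive_control"`,
#'   `"treatment"`.
#' @param toxic_effect_size Dimensionless scale of the positive-control
#'   phenotype shift (0 = indistinguishable from controls).
#' @param noise_sd Additive Gaussian noise SD (scene intensity units, where
#'   structures span roughly 0..1) applied to all eight observed channels.
#' @param seed Integer seed; the same spec (including seed) always renders a
#'   bit-identical field.
#' @return A `bp_scene_spec`.
#' @export
scene_spec <- function(image_size = 256L, n_cells = NULL,
                       batch_id = "batchA", batch_intensity_shift = 1,
                       role = "treatment", toxic_effect_size = 1,
                       noise_sd = 0.02, seed = 1L) {
  if (image_size < 64) abort("scene_spec: image_size must be >= 64")
  n_cells <- n_cells %||% max(1L, round(image_size^2 / 1800))
  if (n_cells < 0) abort("scene_spec: n_cells must be >= 0")
  if (!role %in% c("negative_control", "positive_control", "treatment"))
    abort(sprintf("scene_spec: unknown role '%s'", role))
  if (!length(batch_intensity_shift) %in% c(1L, 5L) ||
      any(batch_intensity_shift <= 0))
    abort("scene_spec: batch_intensity_shift must be positive (length 1 or 5)")
  if (noise_sd < 0) abort("scene_spec: noise_sd must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 n_cells = as.integer(n_cells), batch_id = batch_id,
                 batch_intensity_shift = rep(batch_intensity_shift,
                                             length.out = 5L),
                 role = role, toxic_effect_size = toxic_effect_size,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "bp_scene_spec")
}

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Rasterize an ellipse; returns the in-bounds pixel indices (linear) and
# their normalized radius (1 on the boundary).
ellipse_pixels <- function(H, cx, cy, a, b, phi) {
  r <- max(a, b)
  rows <- max(1L, floor(cx - r)):min(H, ceiling(cx + r))
  cols <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  dx <- outer(rows - cx, rep(1, length(cols)))
  dy <- outer(rep(1, length(rows)), cols - cy)
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  nr <- sqrt(u^2 + v^2)
  keep <- nr <= 1
  idx <- outer(rows, (cols - 1L) * H, "+")
  list(idx = idx[keep], nr = nr[keep])
}

# 1-px-wide segment between two points, sampled at sub-pixel steps.
segment_pixels <- function(H, p1, p2) {
  len <- sqrt(sum((p2 - p1)^2))
  t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.4)))
  px <- round(p1[1] + t * (p2[1] - p1[1]))
  py <- round(p1[2] + t * (p2[2] - p1[2]))
  ok <- px >= 1 & px <= H & py >= 1 & py <= H
  unique(px[ok] + (py[ok] - 1L) * H)
}

smooth_noise_field <- function(H, sigma) {
  f <- EBImage::gblur(matrix(rnorm(H * H), H, H), sigma = sigma)
  (f - min(f)) / (max(f) - min(f) + 1e-12)
}

#' Render one synthetic paired field
#'
#' Deterministically maps a [scene_spec()] to a paired brightfield /
#' fluorescent field. Channel content: DNA = nucleus masks; ER = cytoplasm
#' texture; RNA = dim cytoplasm plus bright nucleolar spots; AGP = membrane
#' rim plus thin (~1 px) filaments; Mito = small granular puncta. The three
#' brightfield planes are linear mixtures of the scene blurred with
#' plane-specific defocus widths (sigma 3, 1, 2 px for z-4um, focus, z+4um),
#' so coarse structure is recoverable from brightfield while the fine AGP
#' filaments and Mito puncta are partially lost — the property that makes
#' those channels the hardest to predict.
#'
#' @param spec A [scene_spec()].
#' @return A `bp_field`: list with `brightfield` `(H, W, 3)`, `fluorescent`
#'   `(H, W, 5)` (noisy, batch-shifted), `clean_fluorescent` (noise-free,
#'   unshifted), `masks` (`nuclei` and `cells` label matrices), and
#'   `metadata`.
#' @export
generate_field <- function(spec) {
  if (!inherits(spec, "bp_scene_spec")) spec <- do.call(scene_spec, spec)
  with_preserved_rng(spec$seed, {
    H <- spec$image_size
    sc <- H / 256
    toxic <- spec$role == "positive_control"
    size_factor <- if (toxic) 1 + 0.4 * spec$toxic_effect_size else 1
    mito_factor <- if (toxic) 1 / (1 + spec$toxic_effect_size) else 1

    # -- place cells (nucleus overlap rejection keeps the count exact) ----
    n <- spec$n_cells
    cells <- list()
    tries <- 0L
    while (length(cells) < n) {
      if ((tries <- tries + 1L) > 400L * max(n, 1L))
        abort(sprintf("could not place %d non-overlapping cells at size %d",
                      n, H))
      a <- runif(1, 5, 8) * sc * size_factor
      b <- runif(1, 5, 8) * sc * size_factor
      cs <- runif(1, 1.9, 2.4)
      r_cell <- max(a, b) * cs
      cx <- runif(1, 1 + r_cell * 0.6, H - r_cell * 0.6)
      cy <- runif(1, 1 + r_cell * 0.6, H - r_cell * 0.6)
      ok <- TRUE
      for (cl in cells) {
        lim <- (max(a, b) + max(cl$a, cl$b)) * 1.1 + 4 * sc
        if ((cx - cl$cx)^2 + (cy - cl$cy)^2 < lim^2) { ok <- FALSE; break }
      }
      if (ok) cells[[length(cells) + 1L]] <-
          list(cx = cx, cy = cy, a = a, b = b, phi = runif(1, 0, pi),
               cell_scale = cs, intensity = runif(1, 0.7, 1))
    }

    nuc_lab <- matrix(0L, H, H)
    cell_lab <- matrix(0L, H, H)
    cell_nr <- matrix(Inf, H, H)   # normalized cell radius, for rims
    dna <- er <- rna <- agp <- mito <- matrix(0, H, H)

    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      np <- ellipse_pixels(H, cl$cx, cl$cy, cl$a, cl$b, cl$phi)
      cp <- ellipse_pixels(H, cl$cx, cl$cy, cl$a * cl$cell_scale,
                           cl$b * cl$cell_scale, cl$phi)
      closer <- cp$nr < cell_nr[cp$idx]
      cell_lab[cp$idx[closer]] <- i
      cell_nr[cp$idx[closer]] <- cp$nr[closer]
      nuc_lab[np$idx] <- i
      dna[np$idx] <- cl$intensity * (1 - 0.25 * np$nr^2)

      # nucleolar RNA spots
      for (k in seq_len(sample(1:3, 1))) {
        ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.45)
        sp <- ellipse_pixels(H, cl$cx + rad * cl$a * cos(ang),
                             cl$cy + rad * cl$b * sin(ang),
                             max(1.2, runif(1, 1.5, 2.5) * sc),
                             max(1.2, runif(1, 1.5, 2.5) * sc), 0)
        rna[sp$idx] <- pmax(rna[sp$idx], cl$intensity)
      }

      # thin AGP filaments (approximately 1 px wide)
      for (k in seq_len(rpois(1, 4))) {
        a1 <- runif(1, 0, 2 * pi); a2 <- a1 + runif(1, pi / 2, 3 * pi / 2)
        r1 <- runif(1, 0.3, 0.92); r2 <- runif(1, 0.3, 0.92)
        p1 <- c(cl$cx + r1 * cl$a * cl$cell_scale * cos(a1),
                cl$cy + r1 * cl$b * cl$cell_scale * sin(a1))
        p2 <- c(cl$cx + r2 * cl$a * cl$cell_scale * cos(a2),
                cl$cy + r2 * cl$b * cl$cell_scale * sin(a2))
        agp[segment_pixels(H, p1, p2)] <- 0.7 * cl$intensity
      }
    }

    cyto <- cell_lab > 0 & nuc_lab == 0
    cellmask <- cell_lab > 0

    tex_er <- smooth_noise_field(H, 1.5 * sc + 0.5)
    er <- 0.25 * (nuc_lab > 0) + cyto * (0.45 + 0.55 * tex_er)
    rna <- rna + 0.3 * cyto
    rim <- cellmask & cell_nr > 0.86
    agp[rim] <- pmax(agp[rim], 0.9)
    agp <- agp + 0.15 * cyto
    # AGP filaments only survive inside cells
    agp[!cellmask] <- 0

    # Mito puncta: granular 1-2 px dots in the cytoplasm
    mito_density <- 0.030 * mito_factor
    cyto_idx <- which(cyto)
    n_punc <- rpois(1, length(cyto_idx) * mito_density)
    if (n_punc > 0 && length(cyto_idx)) {
      pidx <- sample(cyto_idx, min(n_punc, length(cyto_idx)))
      mito[pidx] <- runif(length(pidx), 0.6, 1)
      two_px <- runif(length(pidx)) < 0.5
      nb <- pidx[two_px] + sample(c(1L, -1L, H, -H), sum(two_px),
                                  replace = TRUE)
      nb <- nb[nb >= 1 & nb <= H * H]
      mito[nb] <- pmax(mito[nb], runif(length(nb), 0.6, 1))
    }
    mito <- mito + 0.12 * cyto

    blur <- function(x, s) EBImage::gblur(x, sigma = max(s, 0.25))
    fl <- array(0, c(H, H, 5))
    fl[, , 1] <- blur(dna, 0.8 * sc + 0.2)
    fl[, , 2] <- blur(er, 0.8 * sc + 0.2)
    fl[, , 3] <- blur(rna, 0.6)
    fl[, , 4] <- blur(agp, 0.5)
    fl[, , 5] <- blur(mito, 0.5)

    # brightfield: channel mixtures under plane-specific defocus
    mix <- rbind(c(0.50, 0.20, 0.20, 0.10, 0.10),
                 c(0.60, 0.30, 0.15, 0.25, 0.20),
                 c(0.30, 0.45, 0.35, 0.15, 0.30))
    base <- c(0.90, 0.85, 0.80)
    sig <- c(3, 1, 2) * sc
    bf <- array(0, c(H, H, 3))
    for (p in 1:3) {
      m <- mix[p, 1] * fl[, , 1] + mix[p, 2] * fl[, , 2] +
        mix[p, 3] * fl[, , 3] + mix[p, 4] * fl[, , 4] + mix[p, 5] * fl[, , 5]
      bf[, , p] <- base[p] - blur(m, sig[p]) + 0.05 * blur(cellmask * 1, sig[p])
    }

    clean <- fl
    for (c in 1:5) fl[, , c] <- fl[, , c] * spec$batch_intensity_shift[c]
    if (spec$noise_sd > 0) {
      fl <- fl + array(rnorm(length(fl), sd = spec$noise_sd), dim(fl))
      bf <- bf + array(rnorm(length(bf), sd = spec$noise_sd), dim(bf))
    }
    dimnames(fl) <- list(NULL, NULL, cp_channels())
    dimnames(clean) <- list(NULL, NULL, cp_channels())
    dimnames(bf) <- list(NULL, NULL, bf_planes())

    structure(list(brightfield = bf, fluorescent = fl,
                   clean_fluorescent = clean,
                   masks = list(nuclei = nuc_lab, cells = cell_lab),
                   metadata = list(batch_id = spec$batch_id, well_id = NA,
                                   field_id = NA, role = spec$role),
                   spec = spec),
              class = "bp_field")
  })
}

#' @export
print.bp_field <- function(x, ...) {
  d <- dim(x$brightfield)
  cat(sprintf("<bp_field> %dx%d, %s, batch %s, role %s\n", d[1], d[2],
              paste0(d[3], "+", dim(x$fluorescent)[3], " channels"),
              x$metadata$batch_id, x$metadata$role))
  invisible(x)
}

#' Generate a dataset of synthetic fields on disk
#'
#' Renders `n_fields` fields, cycling over the batch templates, writes one
#' 16-bit TIFF per channel (plus the two segmentation label masks) and
#' returns the manifest. Per-field seeds are derived deterministically from
#' `seed`, so the same call reproduces a byte-identical TIFF tree.
#'
#' @param n_fields Number of fields.
#' @param batch_plan List of [scene_spec()] templates, one per batch; each
#'   field inherits its template's batch id, intensity shift and rendering
#'   parameters.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param role_probs Named probabilities used to draw each field's role;
#'   `NULL` keeps every template's own role.
#' @return Manifest tibble: one row per field with metadata and one path
#'   column per written image.
#' @export
generate_dataset <- function(n_fields, batch_plan, out_dir,
                             seed = 1L,
                             role_probs = c(negative_control = 0.3,
                                            positive_control = 0.1,
                                            treatment = 0.6)) {
  if (!length(batch_plan)) abort("generate_dataset: empty batch_plan")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create '%s'", out_dir))
  rows <- with_preserved_rng(seed, {
    roles <- if (is.null(role_probs)) NULL else {
      # proportional counts (not a random draw), so small datasets always
      # carry both control classes
      cnt <- round(role_probs / sum(role_probs) * n_fields)
      if (n_fields >= 3) {
        cnt[c("negative_control", "positive_control")] <-
          pmax(cnt[c("negative_control", "positive_control")], 1L)
      }
      while (sum(cnt) > n_fields) cnt["treatment"] <- cnt["treatment"] - 1L
      while (sum(cnt) < n_fields) cnt["treatment"] <- cnt["treatment"] + 1L
      sample(rep(names(cnt), cnt))
    }
    lapply(seq_len(n_fields), function(i) {
      tmpl <- batch_plan[[(i - 1L) %% length(batch_plan) + 1L]]
      sp <- tmpl
      sp$seed <- as.integer((seed * 7919 + i * 104729) %% 2147483629)
      if (!is.null(roles)) sp$role <- roles[i]
      f <- generate_field(sp)
      f$metadata$field_id <- sprintf("f%04d", i)
      f$metadata$well_id <- sprintf("%s_w%03d", sp$batch_id, i)
      paths <- write_field(f, out_dir)
      dplyr::bind_cols(
        tibble(field_id = f$metadata$field_id, batch = sp$batch_id,
               well = f$metadata$well_id, role = sp$role),
        as_tibble(as.list(paths)))
    })
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

# Feature names follow the CellProfiler-style convention
# Compartment_FeatureType_Channel_Detail used by the whole profiling stage.
make_feature_names <- function(n) {
  comps <- cp_compartments()
  types <- cp_feature_types()
  chans <- c(cp_channels(), "none")
  out <- character(n)
  for (i in seq_len(n)) {
    ty <- types[(i - 1L) %% length(types) + 1L]
    ch <- if (ty %in% c("AreaShape", "Neighbors")) "none"
      else chans[(i - 1L) %% 5L + 1L]
    out[i] <- paste(comps[(i - 1L) %% 3L + 1L], ty, ch,
                    sprintf("f%03d", i), sep = "_")
  }
  out
}

# Feature names known to be unreliable; mirrored in
# inst/extdata/blocklist_synthetic.txt for the command-line pipeline.
default_blocklist <- function() {
  c("Nuclei_Colocalization_AGP_costes", "Cells_Colocalization_DNA_manders",
    "Cytoplasm_Granularity_Mito_g14", "Cells_Texture_ER_saturation")
}

#' Generate a synthetic well-level feature table
#'
#' Builds a Gaussian feature matrix with the annotation naming convention of
#' the profiling stage and a set of planted violations used to validate
#' feature selection: a known set of features with >5% missing values, pairs
#' of near-duplicate features (Pearson r > 0.9), features carrying blocklist
#' names, and toxic wells shifted by `effect_size` on a known feature
#' subset. Roles are assigned so the toxicity stage can run directly:
#' negative controls, positive controls (toxic), toxic treatments and inert
#' treatments, with the truth recorded in `truth_toxic`.
#'
#' @param n_wells Number of wells (rows).
#' @param n_features Number of features (columns); must exceed
#'   `2 * n_duplicate_pairs` plus the planted NaN and blocklist features.
#' @param fraction_nan Fraction of features given >5% missing values.
#' @param n_duplicate_pairs Number of planted high-correlation pairs.
#' @param n_toxic Number of toxic wells (split between positive controls and
#'   toxic treatments).
#' @param effect_size Mean shift applied to toxic wells on the planted
#'   feature subset (0 = no phenotype).
#' @param seed Integer seed.
#' @param n_blocklisted Features renamed to blocklist entries.
#' @param prop_negative Fraction of wells labelled negative controls.
#' @param batch_effect Mean shift of batch B on a random third of features.
#' @return Tibble with metadata columns (`well_id`, `batch`, `role`,
#'   `truth_toxic`) and one column per feature; the `"planted"` attribute
#'   records which features were manipulated.
#' @export
generate_feature_table <- function(n_wells = 96L, n_features = 60L,
                                   fraction_nan = 0.1,
                                   n_duplicate_pairs = 3L, n_toxic = 10L,
                                   effect_size = 2, seed = 1L,
                                   n_blocklisted = 2L, prop_negative = 0.3,
                                   batch_effect = 0.5) {
  n_nan <- round(fraction_nan * n_features)
  reserved <- 2L * n_duplicate_pairs + n_nan + n_blocklisted
  if (n_features <= reserved)
    abort(sprintf(
      "generate_feature_table: n_features (%d) must exceed the %d planted features",
      n_features, reserved))
  n_neg <- max(3L, round(prop_negative * n_wells))
  n_pos <- ceiling(n_toxic / 2)
  if (n_toxic + n_neg >= n_wells)
    abort("generate_feature_table: too many toxic + control wells")

  with_preserved_rng(seed, {
    nms <- make_feature_names(n_features)
    if (n_blocklisted > 0)
      nms[reserved - n_blocklisted + seq_len(n_blocklisted)] <-
        default_blocklist()[seq_len(n_blocklisted)]
    m <- matrix(rnorm(n_wells * n_features), n_wells, n_features)

    dup_a <- seq_len(n_duplicate_pairs)
    dup_b <- n_duplicate_pairs + seq_len(n_duplicate_pairs)
    for (j in seq_len(n_duplicate_pairs))
      m[, dup_b[j]] <- m[, dup_a[j]] + rnorm(n_wells, sd = 0.3)

    nan_feats <- 2L * n_duplicate_pairs + seq_len(n_nan)
    for (j in nan_feats)
      m[sample.int(n_wells, ceiling(0.08 * n_wells) + 1L), j] <- NA_real_

    roles <- rep("treatment", n_wells)
    roles[seq_len(n_neg)] <- "negative_control"
    roles[n_neg + seq_len(n_pos)] <- "positive_control"
    truth_toxic <- logical(n_wells)
    truth_toxic[n_neg + seq_len(n_toxic)] <- TRUE

    clean <- setdiff(seq_len(n_features), c(dup_a, dup_b, nan_feats,
                                            reserved - n_blocklisted +
                                              seq_len(n_blocklisted)))
    toxic_feats <- sample(clean, max(3L, round(0.2 * length(clean))))
    m[truth_toxic, toxic_feats] <- m[truth_toxic, toxic_feats] + effect_size

    batch <- rep(c("batchA", "batchB"), length.out = n_wells)
    if (batch_effect != 0) {
      bfeat <- sample(clean, max(1L, round(length(clean) / 3)))
      m[batch == "batchB", bfeat] <- m[batch == "batchB", bfeat] + batch_effect
    }

    colnames(m) <- nms
    out <- dplyr::bind_cols(
      tibble(well_id = sprintf("w%03d", seq_len(n_wells)), batch = batch,
             role = roles, truth_toxic = truth_toxic),
      as_tibble(m))
    attr(out, "planted") <- list(
      duplicate_pairs = tibble(a = nms[dup_a], b = nms[dup_b]),
      nan_features = nms[nan_feats],
      blocklist_features = if (n_blocklisted > 0)
        nms[reserved - n_blocklisted + seq_len(n_blocklisted)] else character(),
      toxic_features = nms[toxic_feats])
    out
  })
}
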