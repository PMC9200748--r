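# Morphological profiling: a lightweight stand-in feature extractor for
# synthetic images (real CellProfiler-style tables are accepted anywhere a
# feature table is), well-level aggregation, the four-rule feature
# selection, grouped predicted-vs-truth correlations, and 2-D embedding.

profile_metadata_cols <- function() {
  c("well_id", "field_id", "cell_id", "batch", "role", "truth_toxic",
    "source")
}

feature_columns <- function(table) {
  setdiff(names(table), profile_metadata_cols())
}

#' Parse annotation triples from feature names
#'
#' Feature names follow the CellProfiler-style convention
#' `Compartment_FeatureType_Channel_Detail` (channel `none` for
#' channel-independent features such as area/shape and neighbors).
#'
#' @param features Character vector of feature names.
#' @return Tibble with `feature`, `compartment`, `feature_type`, `channel`.
#' @export
parse_feature_names <- function(features) {
  parts <- strsplit(features, "_", fixed = TRUE)
  tibble(feature = features,
         compartment = vapply(parts, `[`, "", 1),
         feature_type = vapply(parts, `[`, "", 2),
         channel = vapply(parts, `[`, "", 3))
}

region_stats <- function(intensity, region_idx) {
  v <- intensity[region_idx]
  c(mean = mean(v), integrated = sum(v))
}

#' Extract stand-in morphological features from one field
#'
#' A compact proxy for a segmentation-based feature-extraction pipeline,
#' emitting the same annotation schema: per cell and per compartment
#' (Cells, Cytoplasm, Nuclei) x channel it measures mean and integrated
#' intensity, a texture proxy (variance of the local 3x3-mean residual), a
#' granularity proxy (difference-of-Gaussian energy), radial-distribution
#' ring fractions (three equal-width rings from the compartment centroid),
#' plus channel-independent area/shape and neighbor-count features.
#'
#' @param fluorescent `(H, W, 5)` stack to measure (ground truth or
#'   prediction).
#' @param masks List with `nuclei` and `cells` label matrices (same labels).
#' @param well_id,field_id Identifiers copied into the output rows.
#' @return Tibble with one row per cell; an empty mask yields a single
#'   all-missing row.
#' @export
extract_standin_features <- function(fluorescent, masks, well_id = "well",
                                     field_id = "field") {
  nuc <- masks$nuclei
  cel <- masks$cells
  H <- nrow(nuc)
  ids <- sort(setdiff(unique(as.integer(cel)), 0L))
  ch <- cp_channels()

  # per-channel helper images, computed once
  local_dev <- lapply(1:5, function(c) {
    x <- fluorescent[, , c]
    x - EBImage::filter2(x, matrix(1 / 9, 3, 3))
  })
  dog <- lapply(1:5, function(c) {
    x <- fluorescent[, , c]
    (EBImage::gblur(x, 1) - EBImage::gblur(x, 2))^2
  })

  centers <- lapply(ids, function(i) {
    idx <- which(cel == i)
    c(mean((idx - 1) %% H + 1), mean((idx - 1) %/% H + 1))
  })

  rows <- lapply(seq_along(ids), function(ii) {
    i <- ids[ii]
    regions <- list(Cells = which(cel == i),
                    Nuclei = which(nuc == i),
                    Cytoplasm = which(cel == i & nuc != i))
    out <- list(well_id = well_id, field_id = field_id,
                cell_id = sprintf("%s_c%03d", field_id, i))
    for (comp in names(regions)) {
      idx <- regions[[comp]]
      if (!length(idx)) next
      rr <- (idx - 1) %% H + 1
      cc <- (idx - 1) %/% H + 1
      cr <- mean(rr); cc0 <- mean(cc)
      rad <- sqrt((rr - cr)^2 + (cc - cc0)^2)
      rmax <- max(rad, 1e-9)
      ring <- pmin(3L, floor(rad / rmax * 3) + 1L)
      out[[paste(comp, "AreaShape", "none", "area", sep = "_")]] <-
        length(idx)
      bbox <- (max(rr) - min(rr) + 1) * (max(cc) - min(cc) + 1)
      out[[paste(comp, "AreaShape", "none", "extent", sep = "_")]] <-
        length(idx) / bbox
      for (c in 1:5) {
        x <- fluorescent[, , c]
        v <- x[idx]
        out[[paste(comp, "Intensity", ch[c], "mean", sep = "_")]] <- mean(v)
        out[[paste(comp, "Intensity", ch[c], "integrated", sep = "_")]] <-
          sum(v)
        out[[paste(comp, "Texture", ch[c], "localvar", sep = "_")]] <-
          stats::var(local_dev[[c]][idx])
        out[[paste(comp, "Granularity", ch[c], "dog", sep = "_")]] <-
          mean(dog[[c]][idx])
        tot <- sum(v)
        for (j in 1:3)
          out[[paste(comp, "RadialDistribution", ch[c],
                     paste0("frac", j), sep = "_")]] <-
            if (abs(tot) > 1e-12) sum(v[ring == j]) / tot else NA_real_
      }
    }
    r_i <- sqrt(length(regions$Cells) / pi)
    nb <- sum(vapply(seq_along(ids), function(jj) {
      jj != ii && sqrt(sum((centers[[jj]] - centers[[ii]])^2)) < 5 * r_i
    }, logical(1)))
    out[["Cells_Neighbors_none_count"]] <- nb
    as_tibble(out)
  })
  if (!length(rows)) {
    return(tibble(well_id = well_id, field_id = field_id,
                  cell_id = NA_character_))
  }
  dplyr::bind_rows(rows)
}

#' Aggregate per-cell or per-image features to profiles
#'
#' Median aggregation per group, excluding missing values per feature; a
#' group whose values are all missing stays missing.
#'
#' @param table Feature tibble (rows = cells or images).
#' @param level `"well"` (groups by `well_id`) or `"image"` (by `field_id`).
#' @return One profile row per group; metadata columns keep their first
#'   value within the group.
#' @export
aggregate_profiles <- function(table, level = c("well", "image")) {
  level <- match.arg(level)
  key <- switch(level, well = "well_id", image = "field_id")
  if (!key %in% names(table))
    abort(sprintf("aggregate_profiles: missing grouping column '%s'", key))
  feats <- feature_columns(table)
  meta <- setdiff(intersect(profile_metadata_cols(), names(table)),
                  c(key, "cell_id"))
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(meta), dplyr::first),
      dplyr::across(dplyr::all_of(feats),
                    ~ if (all(is.na(.x))) NA_real_ else
                      median(.x, na.rm = TRUE)),
      .groups = "drop")
}

#' Four-rule feature selection
#'
#' Applies, in order: (1) drop features with more than `nan_threshold`
#' missing values or more than `zero_threshold` exact zeros; (2) drop
#' blocklisted features; (3) drop features correlating above `cor_threshold`
#' (absolute Pearson) with another feature — features are scanned in order
#' of decreasing variance and dropped when they correlate with an
#' already-kept feature, so the more variable member of a pair survives;
#' (4) drop features whose standard deviation over the negative-control
#' (DMSO) wells exceeds `sd_threshold` (computed on the values as given,
#' i.e. pre-normalization). When the table carries a `source` column, all
#' statistics are computed on the `ground_truth` rows only, so predicted
#' values can never influence the survivor set.
#'
#' @param table Profile tibble.
#' @param blocklist Character vector of feature names to drop by rule 2.
#' @param dmso_mask Logical mask of negative-control rows; defaults to
#'   `role == "negative_control"`.
#' @param nan_threshold,zero_threshold,cor_threshold,sd_threshold Rule
#'   thresholds (defaults 0.05, 0.05, 0.9, 15).
#' @return A `bp_selection_report`: surviving feature names plus per-rule
#'   drop lists. Use [apply_selection()] to subset any table with it.
#' @export
select_features <- function(table, blocklist = character(),
                            dmso_mask = NULL,
                            nan_threshold = 0.05, zero_threshold = 0.05,
                            cor_threshold = 0.9, sd_threshold = 15) {
  if (!nrow(table)) abort("select_features: empty table")
  if ("source" %in% names(table)) {
    gt <- table$source == "ground_truth"
    if (!any(gt)) abort("select_features: no ground_truth rows")
    table <- table[gt, ]
  }
  feats <- feature_columns(table)
  dmso_mask <- dmso_mask %||% (table$role == "negative_control")
  if (!any(dmso_mask))
    abort("select_features: no DMSO (negative control) rows")

  x <- as.matrix(table[, feats])
  n <- nrow(x)

  frac_nan <- colMeans(is.na(x))
  frac_zero <- colMeans(x == 0, na.rm = TRUE)
  frac_zero[is.nan(frac_zero)] <- 0
  drop1 <- feats[frac_nan > nan_threshold | frac_zero > zero_threshold]

  keep <- setdiff(feats, drop1)
  drop2 <- intersect(keep, blocklist)
  keep <- setdiff(keep, drop2)

  vs <- apply(x[, keep, drop = FALSE], 2, stats::var, na.rm = TRUE)
  ord <- keep[order(vs, decreasing = TRUE)]
  kept <- character()
  drop3 <- character()
  if (length(ord)) {
    cm <- suppressWarnings(
      cor(x[, ord, drop = FALSE], use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0
    for (f in ord) {
      if (length(kept) && any(abs(cm[f, kept]) > cor_threshold))
        drop3 <- c(drop3, f)
      else kept <- c(kept, f)
    }
  }

  sds <- apply(x[dmso_mask, kept, drop = FALSE], 2, sd, na.rm = TRUE)
  drop4 <- kept[!is.na(sds) & sds > sd_threshold]
  kept <- setdiff(kept, drop4)

  structure(list(selected = kept[order(match(kept, feats))],
                 dropped = list(missing = drop1, blocklist = drop2,
                                correlated = drop3, variable = drop4),
                 thresholds = c(nan = nan_threshold, zero = zero_threshold,
                                cor = cor_threshold, sd = sd_threshold),
                 n_input = length(feats)),
            class = "bp_selection_report")
}

#' @export
print.bp_selection_report <- function(x, ...) {
  d <- lengths(x$dropped)
  cat(sprintf(
    "<bp_selection_report> %d/%d features kept (dropped: %d missing, %d blocklist, %d correlated, %d variable)\n",
    length(x$selected), x$n_input, d["missing"], d["blocklist"],
    d["correlated"], d["variable"]))
  invisible(x)
}

#' @rdname select_features
#' @param report A `bp_selection_report`.
#' @export
apply_selection <- function(table, report) {
  meta <- intersect(profile_metadata_cols(), names(table))
  table[, c(meta, report$selected)]
}

#' Grouped predicted-versus-truth feature correlation
#'
#' For every feature, the Spearman rank correlation (midranks for ties)
#' across wells between the predicted-source and ground-truth values; group
#' means are reported by (compartment, channel, feature type). Zero-variance
#' features have undefined rank correlation and are reported missing and
#' excluded from group means.
#'
#' @param pred,truth Profile tibbles with identical feature columns and well
#'   sets.
#' @return A `bp_feature_correlation`: `per_feature` tibble, `groups` tibble
#'   (mean correlation and feature count per annotation cell), and a
#'   `summary` list (overall mean, top-decile mean, count of features with
#'   r > 0.8).
#' @export
grouped_feature_correlation <- function(pred, truth) {
  fp <- feature_columns(pred)
  ft <- feature_columns(truth)
  if (!setequal(fp, ft))
    abort(paste0("feature sets differ; e.g. ",
                 paste(head(c(setdiff(fp, ft), setdiff(ft, fp)), 4),
                       collapse = ", ")))
  if (!all(pred$well_id %in% truth$well_id))
    abort("pred contains wells absent from truth")
  truth <- truth[match(pred$well_id, truth$well_id), ]
  rho <- vapply(fp, function(f) {
    a <- pred[[f]]; b <- truth[[f]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok], method = "spearman")
  }, numeric(1))
  per_feature <- parse_feature_names(fp) |>
    dplyr::mutate(rho = unname(rho))
  groups <- per_feature |>
    dplyr::group_by(.data$compartment, .data$channel, .data$feature_type) |>
    dplyr::summarise(mean_rho = mean(.data$rho, na.rm = TRUE),
                     n_features = dplyr::n(), .groups = "drop")
  ok <- !is.na(per_feature$rho)
  r <- per_feature$rho[ok]
  summary <- list(
    mean_correlation = mean(r),
    top_decile_mean = if (length(r)) mean(sort(r, decreasing = TRUE)[
      seq_len(max(1, floor(length(r) / 10)))]) else NA_real_,
    n_above_0.8 = sum(r > 0.8),
    n_features = length(r))
  structure(list(per_feature = per_feature, groups = groups,
                 summary = summary),
            class = "bp_feature_correlation")
}

#' @export
print.bp_feature_correlation <- function(x, ...) {
  cat(sprintf(
    "<bp_feature_correlation> %d features, mean rho %.3f, %d features > 0.8\n",
    x$summary$n_features, x$summary$mean_correlation, x$summary$n_above_0.8))
  invisible(x)
}

#' Embed profiles in two dimensions
#'
#' UMAP embedding (default) with the profiling-stage parameters
#' `n_neighbors = 15`, `min_dist = 0.8`, `n_components = 2`, or a principal
#' component projection as the confirmatory alternative. The UMAP
#' implementation is the package's own compact version of the algorithm
#' (fuzzy k-NN graph, cross-entropy layout with negative sampling) with a
#' seeded, reproducible layout.
#'
#' @param profiles Profile tibble (complete feature values; missing entries
#'   are median-imputed per feature).
#' @param method `"umap"` or `"pca"`.
#' @param n_neighbors,min_dist,n_components UMAP parameters.
#' @param seed Layout seed.
#' @param n_epochs UMAP optimization epochs.
#' @return Tibble of metadata plus `dim1`, `dim2`; class `bp_embedding`.
#' @export
embed_profiles <- function(profiles, method = c("umap", "pca"),
                           n_neighbors = 15L, min_dist = 0.8,
                           n_components = 2L, seed = 42L, n_epochs = 200L) {
  method <- match.arg(method)
  if (n_components != 2L)
    abort("embed_profiles: only n_components = 2 is supported")
  feats <- feature_columns(profiles)
  x <- as.matrix(profiles[, feats])
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- median(x[, j], na.rm = TRUE)
  }
  if (method == "pca") {
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    emb <- pc$x[, 1:2, drop = FALSE]
  } else {
    if (nrow(x) < n_neighbors + 1)
      abort(sprintf("embed_profiles: need at least n_neighbors + 1 = %d rows",
                    n_neighbors + 1))
    emb <- umap_embed(x, n_neighbors, min_dist, seed, n_epochs)
  }
  meta <- intersect(profile_metadata_cols(), names(profiles))
  out <- dplyr::bind_cols(profiles[, meta],
                          tibble(dim1 = emb[, 1], dim2 = emb[, 2]))
  structure(out, class = c("bp_embedding", class(out)),
            method = method,
            params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                          seed = seed))
}

# Fit the UMAP low-dimensional similarity curve 1/(1 + a d^(2b)) to the
# target exp(-(d - min_dist)) beyond min_dist (1 inside it).
umap_ab <- function(min_dist, spread = 1) {
  d <- seq(0, spread * 3, length.out = 300)
  target <- ifelse(d <= min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(p) {
    w <- 1 / (1 + exp(p[1]) * d^(2 * exp(p[2])))
    sum((w - target)^2)
  }
  p <- stats::optim(c(0, 0), obj)$par
  c(a = exp(p[1]), b = exp(p[2]))
}

umap_embed <- function(x, n_neighbors, min_dist, seed, n_epochs) {
  with_preserved_rng(seed, {
    n <- nrow(x)
    D <- as.matrix(stats::dist(x))
    k <- n_neighbors
    # fuzzy simplicial set: per-point bandwidth by binary search
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
      d <- D[i, -i]
      nn <- order(d)[seq_len(k)]
      dn <- d[nn]
      rho <- min(dn[dn > 0], Inf)
      if (!is.finite(rho)) rho <- 0
      lo <- 1e-6; hi <- max(dn) + 1
      for (it in 1:50) {
        sig <- (lo + hi) / 2
        s <- sum(exp(-pmax(dn - rho, 0) / sig))
        if (s > log2(k)) hi <- sig else lo <- sig
      }
      cols <- setdiff(seq_len(n), i)[nn]
      P[i, cols] <- exp(-pmax(dn - rho, 0) / sig)
    }
    P <- P + t(P) - P * t(P)
    ab <- umap_ab(min_dist)
    a <- ab["a"]; b <- ab["b"]
    # PCA init scaled to the usual +-10 box
    pc <- prcomp(x, center = TRUE)$x[, 1:2, drop = FALSE]
    y <- pc / max(abs(pc)) * 10 + matrix(rnorm(2 * n, sd = 1e-3), n, 2)
    edges <- which(P > 0 & upper.tri(P), arr.ind = TRUE)
    w <- P[edges]
    wmax <- max(w)
    alpha0 <- 1
    clamp <- function(v) pmax(pmin(v, 4), -4)
    for (ep in seq_len(n_epochs)) {
      alpha <- alpha0 * (1 - (ep - 1) / n_epochs)
      act <- which(runif(length(w)) < w / wmax)
      for (e in act) {
        i <- edges[e, 1]; j <- edges[e, 2]
        diff <- y[i, ] - y[j, ]
        d2 <- sum(diff^2)
        co <- (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
        g <- clamp(co * diff)
        y[i, ] <- y[i, ] + alpha * g
        y[j, ] <- y[j, ] - alpha * g
        for (s in seq_len(5)) {
          jn <- sample.int(n, 1)
          if (jn == i) next
          diff <- y[i, ] - y[jn, ]
          d2 <- sum(diff^2)
          co <- (2 * b) / ((0.001 + d2) * (1 + a * d2^b))
          y[i, ] <- y[i, ] + alpha * clamp(co * diff)
        }
      }
    }
    y
  })
}
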