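#' Z-normalize morphological profiles
#'
#' Per-feature z-score across rows (mean 0, SD 1); zero-variance features
#' map to zero. Applied before K-NN classification so Euclidean distances
#' weight features comparably.
#'
#' @param profiles Profile tibble (>= 2 rows).
#' @return Tibble with the same shape and normalized feature columns.
#' @export
normalize_profiles <- function(profiles) {
  if (nrow(profiles) < 2)
    abort("normalize_profiles: need at least 2 rows")
  for (f in feature_columns(profiles)) {
    v <- profiles[[f]]
    s <- sd(v, na.rm = TRUE)
    profiles[[f]] <- if (is.na(s) || s == 0) rep(0, length(v))
      else (v - mean(v, na.rm = TRUE)) / s
  }
  profiles
}

#' Balanced-resample K-NN toxicity calling with majority voting
#'
#' Classifies every well as toxic or non-toxic against the control wells.
#' Each of `n_runs` runs draws, with replacement, an equal number of
#' training profiles from the positive- and negative-control classes (the
#' larger class count, so the imbalance between control classes cannot bias
#' the vote), then labels every well by the majority class of its `k`
#' nearest Euclidean neighbors among the training draws. Control wells are
#' evaluated leave-self-out: resampled copies of the well being classified
#' are excluded from its own neighbor set. The final call is the majority
#' over runs; a tied vote (exactly `n_runs / 2`) is called non-toxic, the
#' specificity-preserving default.
#'
#' @param profiles Normalized profile tibble with a `role` column containing
#'   `positive_control` and `negative_control` wells.
#' @param k Neighbor count (default 5).
#' @param n_runs Resampling runs (default 100).
#' @param seed Seed for the resampling draws.
#' @return A `bp_toxicity_result`: per-well vote counts and calls; when the
#'   table carries `truth_toxic`, sensitivity and specificity against it
#'   (also via [glance()]).
#' @export
classify_toxicity <- function(profiles, k = 5L, n_runs = 100L, seed = 1L) {
  feats <- feature_columns(profiles)
  if (!length(feats)) abort("classify_toxicity: no feature columns")
  x <- as.matrix(profiles[, feats])
  if (anyNA(x))
    abort("classify_toxicity: profiles contain missing values; run feature selection first")
  pos <- which(profiles$role == "positive_control")
  neg <- which(profiles$role == "negative_control")
  if (!length(pos)) abort("classify_toxicity: no positive controls")
  if (!length(neg)) abort("classify_toxicity: no negative controls")
  n <- nrow(x)
  m <- max(length(pos), length(neg))
  if (2L * m - 1L < k)
    abort("classify_toxicity: too few controls for k neighbors")

  D <- as.matrix(stats::dist(x))
  votes <- integer(n)
  with_preserved_rng(seed, {
    for (r in seq_len(n_runs)) {
      tr_pos <- sample(pos, m, replace = TRUE)
      tr_neg <- sample(neg, m, replace = TRUE)
      train <- c(tr_pos, tr_neg)
      lab <- rep(c(TRUE, FALSE), each = m)
      for (i in seq_len(n)) {
        keep <- train != i          # leave-self-out for control wells
        d <- D[i, train[keep]]
        nn <- order(d)[seq_len(min(k, length(d)))]
        votes[i] <- votes[i] + (sum(lab[keep][nn]) > length(nn) / 2)
      }
    }
  })
  calls <- votes > n_runs / 2
  result <- dplyr::bind_cols(
    profiles[, intersect(c("well_id", "batch", "role", "truth_toxic"),
                         names(profiles))],
    tibble(votes = votes, call = calls))
  conf <- NULL
  if ("truth_toxic" %in% names(profiles) &&
      length(unique(profiles$truth_toxic)) == 2)
    conf <- confusion_metrics(calls, profiles$truth_toxic)
  structure(result, class = c("bp_toxicity_result", class(result)),
            k = k, n_runs = n_runs, confusion = conf)
}

#' Sensitivity and specificity of binary calls
#'
#' @param calls Logical vector of predicted toxicity calls.
#' @param truth Logical vector of true toxicity, same length, with both
#'   classes present.
#' @return Named vector `sensitivity` (TP / (TP + FN)) and `specificity`
#'   (TN / (TN + FP)).
#' @export
confusion_metrics <- function(calls, truth) {
  if (length(calls) != length(truth))
    abort("confusion_metrics: length mismatch")
  truth <- as.logical(truth); calls <- as.logical(calls)
  if (!any(truth) || all(truth))
    abort("confusion_metrics: truth must contain both classes")
  c(sensitivity = sum(calls & truth) / sum(truth),
    specificity = sum(!calls & !truth) / sum(!truth))
}
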