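# ggplot2 views of the pipeline's result objects.

#' Plot per-channel image metrics
#'
#' @param object A `bp_metric_report`.
#' @param ... Unused.
#' @return A ggplot: one panel per metric, bars per channel.
#' @export
autoplot.bp_metric_report <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::mutate(channel = factor(.data$channel, levels = cp_channels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Image metrics by fluorescent channel") +
    ggplot2::theme_minimal()
}

#' Heatmap of grouped feature correlations
#'
#' @param object A `bp_feature_correlation`.
#' @param ... Unused.
#' @return A ggplot tile map of mean Spearman correlation per
#'   (compartment, channel, feature type) cell.
#' @export
autoplot.bp_feature_correlation <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$channel, y = .data$feature_type,
                               fill = .data$mean_rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$mean_rho)), size = 3) +
    ggplot2::facet_wrap(~compartment) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "darkblue",
                                  mid = "white", high = "darkred") +
    ggplot2::labs(x = "channel", y = NULL, fill = "mean rho",
                  title = "Predicted vs ground-truth feature correlations") +
    ggplot2::theme_minimal()
}

#' Scatter plot of an embedding
#'
#' @param object A `bp_embedding` from [embed_profiles()].
#' @param colour_by Metadata column used for point colour (default `role`).
#' @param ... Unused.
#' @return A ggplot scatter of the two embedding dimensions.
#' @export
autoplot.bp_embedding <- function(object, colour_by = "role", ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = sprintf("%s embedding of morphological profiles",
                                  toupper(attr(object, "method"))),
                  x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' Vote distribution of a toxicity result
#'
#' @param object A `bp_toxicity_result`.
#' @param ... Unused.
#' @return A ggplot histogram of toxic votes per well, coloured by role.
#' @export
autoplot.bp_toxicity_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$votes, fill = .data$role)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::geom_vline(xintercept = attr(object, "n_runs") / 2,
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("toxic votes out of %d runs",
                              attr(object, "n_runs")),
                  y = "wells",
                  title = "K-NN toxicity votes by well role") +
    ggplot2::theme_minimal()
}

#' Training history curves
#'
#' @param checkpoint A `bp_checkpoint`.
#' @return A ggplot of validation PCC per channel across epochs.
#' @export
plot_training_history <- function(checkpoint) {
  df <- checkpoint$history |>
    tidyr::pivot_longer(dplyr::starts_with("pcc_"), names_to = "channel",
                        values_to = "pcc") |>
    dplyr::mutate(channel = sub("pcc_", "", .data$channel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$pcc,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = checkpoint$best_epoch,
                        linetype = "dashed") +
    ggplot2::labs(y = "validation PCC",
                  title = sprintf("Validation metrics (%s phase)",
                                  checkpoint$phase)) +
    ggplot2::theme_minimal()
}
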