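# broom-style tidiers for the package's result objects.

#' Tidy a metric report into long form
#'
#' @param x A `bp_metric_report` from [evaluate_field()].
#' @param ... Unused.
#' @return Tibble with `channel`, `metric`, `value`.
#' @export
tidy.bp_metric_report <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"channel", names_to = "metric",
                      values_to = "value")
}

#' @rdname tidy.bp_metric_report
#' @return `glance()`: one row of cross-channel means per metric.
#' @export
glance.bp_metric_report <- function(x, ...) {
  as_tibble(as.list(attr(x, "means")))
}

#' Tidy a feature-selection report
#'
#' @param x A `bp_selection_report` from [select_features()].
#' @param ... Unused.
#' @return Tibble with `feature` and `status` (`kept` or the rule that
#'   dropped it).
#' @export
tidy.bp_selection_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(feature = x$selected, status = "kept"),
    purrr::imap_dfr(x$dropped, function(f, rule)
      tibble(feature = f, status = rule)))
}

#' @rdname tidy.bp_selection_report
#' @export
glance.bp_selection_report <- function(x, ...) {
  tibble(n_input = x$n_input, n_selected = length(x$selected),
         n_missing = length(x$dropped$missing),
         n_blocklist = length(x$dropped$blocklist),
         n_correlated = length(x$dropped$correlated),
         n_variable = length(x$dropped$variable))
}

#' Tidy grouped feature correlations
#'
#' @param x A `bp_feature_correlation`.
#' @param ... Unused.
#' @return The per-feature correlation tibble.
#' @export
tidy.bp_feature_correlation <- function(x, ...) x$per_feature

#' @rdname tidy.bp_feature_correlation
#' @export
glance.bp_feature_correlation <- function(x, ...) {
  as_tibble(x$summary)
}

#' Tidy a toxicity result
#'
#' @param x A `bp_toxicity_result` from [classify_toxicity()].
#' @param ... Unused.
#' @return The per-well vote/call tibble.
#' @export
tidy.bp_toxicity_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "bp_toxicity_result")
  as_tibble(out)
}

#' @rdname tidy.bp_toxicity_result
#' @export
glance.bp_toxicity_result <- function(x, ...) {
  conf <- attr(x, "confusion")
  tibble(n_wells = nrow(x), k = attr(x, "k"), n_runs = attr(x, "n_runs"),
         n_called_toxic = sum(x$call),
         sensitivity = if (is.null(conf)) NA_real_ else conf[["sensitivity"]],
         specificity = if (is.null(conf)) NA_real_ else conf[["specificity"]])
}
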