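#' Canonical channel names
#'
#' All modules share one channel convention: five fluorescent Cell Painting
#' channels in the fixed order DNA, ER, RNA, AGP, Mito, and three brightfield
#' z-planes ordered 4 um below focus, in focus, 4 um above focus. Image
#' stacks are numeric arrays with dim `(H, W, channel)` in these orders.
#'
#' @return `cp_channels()` returns the five fluorescent channel names;
#'   `bf_planes()` the three brightfield plane labels.
#' @examples
#' cp_channels()
#' bf_planes()
#' @export
cp_channels <- function() c("DNA", "ER", "RNA", "AGP", "Mito")

#' @rdname cp_channels
#' @export
bf_planes <- function() c("BFm4", "BF0", "BFp4")

# Compartments and feature types used by the profiling stage (the grouping
# scheme of CellProfiler-style feature names).
cp_compartments <- function() c("Cells", "Cytoplasm", "Nuclei")

cp_feature_types <- function() {
  c("AreaShape", "Colocalization", "Granularity", "Intensity",
    "Neighbors", "RadialDistribution", "Texture")
}
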