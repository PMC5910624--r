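#' Hierarchical clustering with heatmap
#'
#' Agglomerative clustering with centroid linkage on Euclidean distance, run
#' over features and over samples, drawn as a heatmap with both dendrograms.
#' Centroid linkage operates on squared Euclidean distances (merge heights
#' are in squared units) and is known to produce height inversions; any
#' inversions are counted and logged, and the dendrograms are drawn with
#' heights made monotone by cumulative max for display only.
#'
#' @param wide a `feature_table` without missing values.
#' @return list with `hclust_features`, `hclust_samples` (raw hclust objects),
#'   `inversions` (counts), and `plot()`-able via [heatmap_plot()].
#' @export
hierarchical_heatmap <- function(wide) {
  check_no_missing(wide, "hierarchical clustering")
  v <- wide$values
  hc_f <- stats::hclust(stats::dist(v)^2, method = "centroid")
  hc_s <- stats::hclust(stats::dist(t(v))^2, method = "centroid")
  inv <- function(h) sum(diff(h$height) < 0)
  inversions <- c(features = inv(hc_f), samples = inv(hc_s))
  if (any(inversions > 0))
    mf_log("centroid-linkage inversions: ", inversions[["features"]],
           " (features), ", inversions[["samples"]], " (samples)")
  list(hclust_features = hc_f, hclust_samples = hc_s, inversions = inversions)
}

# monotone heights for display (centroid linkage can invert)
monotone_dendrogram <- function(h) {
  h$height <- cummax(h$height)
  stats::as.dendrogram(h)
}

#' Draw the clustered heatmap
#' @param cl result of [hierarchical_heatmap()].
#' @param wide the `feature_table` that was clustered.
#' @return `NULL`; draws on the active device.
#' @export
heatmap_plot <- function(cl, wide) {
  stats::heatmap(wide$values,
                 Rowv = monotone_dendrogram(cl$hclust_features),
                 Colv = monotone_dendrogram(cl$hclust_samples),
                 scale = "none",
                 col = grDevices::hcl.colors(64, "viridis"))
  invisible(NULL)
}
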