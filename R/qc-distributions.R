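#' Distribution summaries across and within samples
#'
#' Two complementary views used to spot consistent anomalies:
#' \describe{
#'   \item{across}{boxplots of `n_random` seeded-random features across
#'     samples, plus one density curve of each sample over all features.}
#'   \item{within}{per-sample boxplot and per-sample density of all that
#'     sample's features.}
#' }
#' When the table has fewer than `n_random` features, all are used (with a
#' warning in the log).
#'
#' @param wide a `feature_table`.
#' @param design optional `design_table` for group coloring.
#' @param group_col design column holding group labels.
#' @param mode `"across"` or `"within"`.
#' @param n_random number of random features in across mode (default 50).
#' @param seed seed for the feature draw.
#' @return list with `selected_features`, `boxplot` (ggplot) and `density`
#'   (ggplot).
#' @export
distribution_summaries <- function(wide, design = NULL, group_col = "group",
                                   mode = c("across", "within"),
                                   n_random = 50, seed = 1) {
  mode <- match.arg(mode)
  if (!is.null(design)) {
    al <- align_tables(wide, design)
    wide <- al$wide; design <- al$design
  }
  v <- wide$values
  grp <- if (!is.null(design)) design_groups(design, group_col) else
    rep("all", ncol(v))

  long <- data.frame(
    featureID = rep(rownames(v), times = ncol(v)),
    sampleID = rep(colnames(v), each = nrow(v)),
    group = rep(grp, each = nrow(v)),
    value = as.vector(v))
  long <- long[!is.na(long$value), ]

  if (mode == "across") {
    nf <- nrow(v)
    if (nf < n_random) {
      mf_log("only ", nf, " features available; using all (requested ",
             n_random, ")", level = "WARN")
      sel <- rownames(v)
    } else {
      sel <- withr::with_seed(seed, sample(rownames(v), n_random))
    }
    sub <- long[long$featureID %in% sel, ]
    sub$featureID <- factor(sub$featureID, levels = sel)
    box <- ggplot2::ggplot(sub, ggplot2::aes(x = featureID, y = value)) +
      ggplot2::geom_boxplot(outlier.size = 0.4, fill = mf_palette(1)) +
      ggplot2::labs(x = NULL, y = "intensity") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
    dens <- ggplot2::ggplot(long,
                            ggplot2::aes(x = value, group = sampleID, color = group)) +
      ggplot2::geom_density() +
      ggplot2::scale_color_manual(values = group_colors(grp)) +
      ggplot2::labs(x = "intensity") + ggplot2::theme_minimal()
  } else {
    sel <- rownames(v)
    box <- ggplot2::ggplot(long, ggplot2::aes(x = sampleID, y = value, fill = group)) +
      ggplot2::geom_boxplot(outlier.size = 0.4) +
      ggplot2::scale_fill_manual(values = group_colors(grp)) +
      ggplot2::labs(x = NULL, y = "intensity") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
    dens <- ggplot2::ggplot(long,
                            ggplot2::aes(x = value, group = sampleID, color = group)) +
      ggplot2::geom_density() +
      ggplot2::scale_color_manual(values = group_colors(grp)) +
      ggplot2::labs(x = "intensity") + ggplot2::theme_minimal()
  }
  list(selected_features = sel, boxplot = box, density = dens, mode = mode)
}
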