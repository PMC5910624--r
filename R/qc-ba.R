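#' Bland-Altman replicate agreement flags
#'
#' For each compared sample pair, plots per-feature difference `d = x - y`
#' against per-feature mean `a = (x + y) / 2` and fits the regression
#' `d = g0 + g1 * a`. A well-behaved replicate pair has slope ~0 and a tight
#' cigar-shaped cloud around `d = 0`. Features that distort the agreement are
#' detected with three standard regression-influence diagnostics:
#' \itemize{
#'   \item |studentized residual| > `qt(0.975, n - 3)`
#'   \item |DFFITS| > `2 * sqrt(2 / n)`
#'   \item Cook's D > `4 / n`
#' }
#' A feature is flagged within a pair when at least one criterion fires, and
#' flagged overall when it fires in any pair.
#'
#' @param wide a `feature_table`.
#' @param design optional `design_table`; with `group_col`, pairs are all
#'   within-group sample pairs (pooled technical replicates). Without a
#'   design, all sample pairs are compared.
#' @param group_col design column holding group labels.
#' @param pairs optional 2-column matrix/data.frame of explicit sample-ID
#'   pairs, overriding the group enumeration.
#' @return list with `feature_flags` (flag_table: `flag_ba`), `sample_flags`
#'   (flag_table: `flag_ba_sample`, 1 when a sample's flagged-feature count
#'   exceeds mean + 2 sd of all counts), `sample_counts` (data.frame),
#'   and `pair_stats` (per-pair slope/intercept and flagged count).
#' @export
bland_altman <- function(wide, design = NULL, group_col = "group", pairs = NULL) {
  if (!is.null(design)) {
    al <- align_tables(wide, design)
    wide <- al$wide; design <- al$design
  }
  sids <- sample_ids(wide)
  if (is.null(pairs)) {
    if (!is.null(design)) {
      grp <- design_groups(design, group_col)
      pairs <- do.call(rbind, lapply(unique(grp), function(g) {
        s <- sids[grp == g]
        if (length(s) < 2) return(NULL)
        t(utils::combn(s, 2))
      }))
    } else {
      pairs <- t(utils::combn(sids, 2))
    }
  } else {
    pairs <- as.matrix(pairs)
  }
  if (is.null(pairs) || nrow(pairs) == 0)
    stop_mf("no sample pairs to compare (need >= 2 samples per group)")

  v <- wide$values
  fids <- rownames(v)
  flagged_any <- stats::setNames(rep(FALSE, length(fids)), fids)
  sample_count <- stats::setNames(rep(0L, length(sids)), sids)
  pair_stats <- data.frame()

  for (p in seq_len(nrow(pairs))) {
    sa <- pairs[p, 1]; sb <- pairs[p, 2]
    if (!all(c(sa, sb) %in% sids)) stop_mf("unknown sample in pair: %s/%s", sa, sb)
    x <- v[, sa]; y <- v[, sb]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 4) {
      mf_log("pair ", sa, "/", sb, ": fewer than 4 shared features, skipped",
             level = "WARN")
      next
    }
    d <- (x - y)[keep]
    a <- ((x + y) / 2)[keep]
    fit <- stats::lm(d ~ a)
    n <- sum(keep)
    rs <- stats::rstudent(fit)
    dff <- stats::dffits(fit)
    cd <- stats::cooks.distance(fit)
    crit <- (abs(rs) > stats::qt(0.975, n - 3)) |
      (abs(dff) > 2 * sqrt(2 / n)) | (cd > 4 / n)
    crit[is.na(crit)] <- FALSE          # e.g. identical samples: zero residual variance
    hit_features <- fids[keep][which(crit)]
    flagged_any[hit_features] <- TRUE
    sample_count[sa] <- sample_count[sa] + length(hit_features)
    sample_count[sb] <- sample_count[sb] + length(hit_features)
    pair_stats <- rbind(pair_stats, data.frame(
      sample_a = sa, sample_b = sb,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      n_features = n, n_flagged = length(hit_features)))
  }

  thresh <- mean(sample_count) + 2 * stats::sd(sample_count)
  if (!is.finite(thresh)) thresh <- Inf
  feature_flags <- flag_table(fids, data.frame(flag_ba = as.integer(flagged_any)))
  sample_flags <- flag_table(sids, data.frame(
    flag_ba_sample = as.integer(sample_count > thresh)), id_col = "sampleID")
  mf_log("Bland-Altman: ", sum(flagged_any), " feature(s) flagged over ",
         nrow(pairs), " pair(s)")
  list(feature_flags = feature_flags,
       sample_flags = sample_flags,
       sample_counts = data.frame(sampleID = sids,
                                  n_flagged = unname(sample_count),
                                  row.names = NULL),
       pair_stats = pair_stats)
}

#' Bland-Altman plot for one sample pair
#'
#' Difference against mean, with the fitted agreement regression and flagged
#' features highlighted in red. The estimated slope is annotated.
#'
#' @param wide a `feature_table`.
#' @param sample_a,sample_b sample IDs to compare.
#' @return a ggplot object.
#' @export
ba_plot <- function(wide, sample_a, sample_b) {
  res <- bland_altman(wide, pairs = cbind(sample_a, sample_b))
  x <- wide$values[, sample_a]; y <- wide$values[, sample_b]
  keep <- !is.na(x) & !is.na(y)
  df <- data.frame(mean = ((x + y) / 2)[keep], diff = (x - y)[keep],
                   flagged = factor(res$feature_flags$flag_ba[keep],
                                    levels = c(0, 1)))
  slope <- res$pair_stats$slope[1]
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff, color = flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         inherit.aes = FALSE,
                         ggplot2::aes(x = mean, y = diff), color = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`0` = "grey30", `1` = "red"),
                                drop = FALSE) +
    ggplot2::labs(title = sprintf("%s vs %s (slope = %.3g)",
                                  sample_a, sample_b, slope),
                  x = "mean of pair", y = "difference") +
    ggplot2::theme_minimal()
}
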