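# Feature-by-feature t-tests and the permutation counterpart. All tests use
# casewise deletion per feature and attach significance flags at 0.05 / 0.01
# / 0.001.

add_sig_flags <- function(df, p_col = "p_value") {
  p <- df[[p_col]]
  df$flag_05 <- as.integer(!is.na(p) & p < 0.05)
  df$flag_01 <- as.integer(!is.na(p) & p < 0.01)
  df$flag_001 <- as.integer(!is.na(p) & p < 0.001)
  df
}

# one-sample t over matrix rows; zero-variance rows resolved by convention:
# mean equal to mu0 -> no evidence (p = 1), otherwise infinite evidence
row_t_one <- function(m, mu0) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  s <- row_sds(m)
  t <- (mu - mu0) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  zero <- !is.na(s) & s == 0
  if (any(zero)) {
    mf_log(sum(zero), " zero-variance feature(s) in one-sample t-test", level = "WARN")
    t[zero] <- ifelse(mu[zero] == mu0, 0, sign(mu[zero] - mu0) * Inf)
    p[zero] <- ifelse(mu[zero] == mu0, 1, 0)
  }
  bad <- n < 2
  t[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(estimate = mu - mu0, statistic = t, df = n - 1, p_value = p)
}

# pooled-variance two-sample t over matrix rows given a logical group-1 mask
row_t_two <- function(m, in1) {
  m1 <- m[, in1, drop = FALSE]; m2 <- m[, !in1, drop = FALSE]
  n1 <- rowSums(!is.na(m1)); n2 <- rowSums(!is.na(m2))
  mu1 <- rowMeans(m1, na.rm = TRUE); mu2 <- rowMeans(m2, na.rm = TRUE)
  ss1 <- rowSums((m1 - mu1)^2, na.rm = TRUE)
  ss2 <- rowSums((m2 - mu2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  est <- mu1 - mu2
  t <- est / se
  p <- 2 * stats::pt(-abs(t), df = df)
  zero <- !is.na(sp2) & sp2 == 0
  t[zero] <- ifelse(est[zero] == 0, 0, sign(est[zero]) * Inf)
  p[zero] <- ifelse(est[zero] == 0, 1, 0)
  bad <- n1 < 1 | n2 < 1 | df < 1
  t[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(estimate = est, statistic = t, df = df, p_value = p)
}

#' Single-group t-test
#'
#' Tests each feature's mean against a fixed value `mu0` (default 0). With a
#' pairing, within-pair differences between the two groups are tested against
#' `mu0` instead, which makes this the paired-difference test.
#'
#' @param wide a `feature_table`.
#' @param design optional `design_table` (required for pairing).
#' @param mu0 null value of the mean.
#' @param group_col,pair_col when both given, samples are matched by
#'   `pair_col` across the two levels of `group_col` and differences
#'   (first level minus second) are tested.
#' @return data.frame: featureID, estimate, statistic, df, p_value and
#'   significance flags at 0.05/0.01/0.001.
#' @export
single_group_ttest <- function(wide, design = NULL, mu0 = 0,
                               group_col = NULL, pair_col = NULL) {
  if (!is.null(design)) {
    al <- align_tables(wide, design)
    wide <- al$wide; design <- al$design
  }
  m <- wide$values
  if (!is.null(group_col) && !is.null(pair_col)) {
    m <- paired_differences(wide, design, group_col, pair_col)
  }
  if (ncol(m) < 2) stop_mf("need at least 2 observations per feature")
  out <- cbind(data.frame(featureID = rownames(m)), row_t_one(m, mu0))
  rownames(out) <- NULL
  add_sig_flags(out)
}

paired_differences <- function(wide, design, group_col, pair_col) {
  grp <- design_groups(design, group_col)
  lev <- unique(grp)
  if (length(lev) != 2) stop_mf("pairing requires exactly 2 groups, found %d", length(lev))
  pair <- as.character(design_column(design, pair_col))
  sids <- sample_ids(design)
  p1 <- pair[grp == lev[1]]; s1 <- sids[grp == lev[1]]
  p2 <- pair[grp == lev[2]]; s2 <- sids[grp == lev[2]]
  common <- intersect(p1, p2)
  if (length(common) < 2) stop_mf("fewer than 2 complete pairs in '%s'", pair_col)
  incomplete <- setdiff(union(p1, p2), common)
  if (length(incomplete))
    mf_log("dropping incomplete pair(s): ", paste(incomplete, collapse = ", "),
           level = "WARN")
  d <- wide$values[, s1[match(common, p1)], drop = FALSE] -
    wide$values[, s2[match(common, p2)], drop = FALSE]
  colnames(d) <- common
  d
}

#' Two-group t-test
#'
#' Unpaired: pooled-variance two-sample t per feature; paired: one-sample t
#' on within-pair differences. The estimate is mean(group 1) - mean(group 2),
#' groups taken in design-file order, and doubles as the volcano-plot x axis.
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param group_col design column holding the two group labels.
#' @param paired use within-pair differences.
#' @param pair_col design column identifying pairs (required when `paired`).
#' @return data.frame: featureID, contrast, estimate, statistic, df, p_value
#'   and significance flags.
#' @export
two_group_ttest <- function(wide, design, group_col = "group",
                            paired = FALSE, pair_col = NULL) {
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  lev <- unique(grp)
  if (length(lev) != 2)
    stop_mf("t-test requires exactly 2 groups, found %d (%s)",
            length(lev), paste(lev, collapse = ", "))
  if (any(table(grp) < 2)) stop_mf("each group needs at least 2 samples")

  if (paired) {
    if (is.null(pair_col)) stop_mf("paired = TRUE requires pair_col")
    d <- paired_differences(wide, design, group_col, pair_col)
    res <- row_t_one(d, 0)
  } else {
    res <- row_t_two(wide$values, grp == lev[1])
  }
  out <- cbind(data.frame(featureID = feature_ids(wide),
                          contrast = paste(lev[1], "-", lev[2])), res)
  rownames(out) <- NULL
  add_sig_flags(out)
}

#' Group comparison by permutation
#'
#' Computes the pooled-variance t-statistic per feature and derives its null
#' distribution by permuting group labels across samples (the same label
#' permutation is applied to every feature; per-feature missing values are
#' dropped casewise). The two-sided p-value uses the add-one estimator
#' `p = (1 + #{|t*| >= |t|}) / (1 + n_perm)`, so p is never exactly zero and
#' always at least `1 / (1 + n_perm)`. With `exact = TRUE`, all distinct
#' label assignments are enumerated instead and
#' `p = #{|t*| >= |t|} / n_assignments` (the observed assignment is one of
#' them).
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param group_col design column holding the two group labels.
#' @param n_perm number of random permutations (warning below 100).
#' @param seed RNG seed.
#' @param exact enumerate all label assignments (feasible for small n).
#' @return data.frame: featureID, contrast, estimate, statistic (observed t),
#'   p_value and significance flags.
#' @export
permutation_test <- function(wide, design, group_col = "group",
                             n_perm = 1000, seed = 1, exact = FALSE) {
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  lev <- unique(grp)
  if (length(lev) != 2) stop_mf("permutation test requires exactly 2 groups")
  if (!exact && n_perm < 100)
    warning("fewer than 100 permutations gives a coarse p-value")

  m <- wide$values
  in1 <- grp == lev[1]
  obs <- row_t_two(m, in1)
  tobs <- abs(obs$statistic)
  tol <- 1e-12   # guard against float jitter in |t*| == |t| comparisons

  if (exact) {
    assignments <- utils::combn(length(grp), sum(in1))
    count <- rep(0L, nrow(m))
    for (j in seq_len(ncol(assignments))) {
      mask <- seq_along(grp) %in% assignments[, j]
      tp <- abs(row_t_two(m, mask)$statistic)
      count <- count + as.integer(!is.na(tp) & tp >= tobs - tol)
    }
    p <- count / ncol(assignments)
  } else {
    count <- rep(0L, nrow(m))
    withr::with_seed(seed, {
      for (b in seq_len(n_perm)) {
        mask <- sample(in1)
        tp <- abs(row_t_two(m, mask)$statistic)
        count <- count + as.integer(!is.na(tp) & tp >= tobs - tol)
      }
    })
    p <- (1 + count) / (1 + n_perm)
  }

  out <- data.frame(featureID = feature_ids(wide),
                    contrast = paste(lev[1], "-", lev[2]),
                    estimate = obs$estimate, statistic = obs$statistic,
                    p_value = p)
  rownames(out) <- NULL
  add_sig_flags(out)
}

#' Volcano plot of a per-feature test result
#'
#' `-log10` raw p-value against the group-mean difference, colored at the
#' three significance levels.
#'
#' @param result data.frame with `estimate` and `p_value` columns (one
#'   contrast).
#' @param title plot title.
#' @return a ggplot object.
#' @export
volcano_plot <- function(result, title = NULL) {
  df <- result[!is.na(result$p_value), ]
  df$level <- cut(df$p_value, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                  labels = c("p < 0.001", "p < 0.01", "p < 0.05", "ns"))
  cols <- c("p < 0.001" = "#D7191C", "p < 0.01" = "#FDAE61",
            "p < 0.05" = "#ABD9E9", "ns" = "grey60")
  ggplot2::ggplot(df, ggplot2::aes(x = estimate, y = -log10(p_value),
                                   color = level)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = -log10(c(0.05, 0.01, 0.001)),
                        linetype = 3, color = "grey50") +
    ggplot2::scale_color_manual(values = cols, drop = FALSE) +
    ggplot2::labs(x = "difference of group means", y = "-log10 raw p",
                  title = title) +
    ggplot2::theme_minimal()
}
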