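#' Retention-time stability flags
#'
#' Two criteria over per-sample retention times of each feature: (1) features
#' in the top `cv_percentile` percent by coefficient of variation
#' (`sd / mean`) of RT across samples, ties broken by feature order so exactly
#' `ceiling(p% * n)` features carry `flag_rt_cv`; (2) features whose RT range
#' (`max - min`) exceeds `abs_threshold` minutes carry `flag_rt_range`.
#' `flag_rt` is the OR of the two. Unstable retention times point at
#' injection, alignment or chromatography problems.
#'
#' @param rt_table a `feature_table` whose values are retention times (minutes)
#'   of each feature in each sample.
#' @param cv_percentile percent of features to flag by CV (default 10).
#' @param abs_threshold absolute RT-range threshold in minutes.
#' @return a `flag_table` over features with columns `flag_rt_cv`,
#'   `flag_rt_range`, `flag_rt`; per-feature CV and range attached as
#'   attribute `metrics`.
#' @export
rt_flags <- function(rt_table, cv_percentile = 10, abs_threshold = 0.2) {
  v <- rt_table$values
  mu <- rowMeans(v, na.rm = TRUE)
  cv <- row_sds(v) / mu
  rng <- apply(v, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 1) return(NA_real_)
    max(r) - min(r)
  })

  undef <- !is.na(mu) & mu == 0
  if (any(undef))
    mf_log("CV undefined (zero mean RT) for feature(s) ",
           paste(rownames(v)[undef], collapse = ", "), "; flagged",
           level = "WARN")

  n <- nrow(v)
  n_flag <- min(n, ceiling(cv_percentile / 100 * n))
  cv_rank <- rank(-replace(cv, is.na(cv), -Inf), ties.method = "first")
  flag_cv <- as.integer(cv_rank <= n_flag | undef)
  flag_rng <- as.integer(!is.na(rng) & rng > abs_threshold)
  out <- flag_table(rownames(v),
                    data.frame(flag_rt_cv = flag_cv,
                               flag_rt_range = flag_rng,
                               flag_rt = as.integer(flag_cv | flag_rng)))
  attr(out, "metrics") <- data.frame(featureID = rownames(v), cv = cv,
                                     rt_range = rng, row.names = NULL)
  mf_log("RT flags: ", sum(out$flag_rt), " of ", n, " features flagged")
  out
}

#' Run-order regression (ROR)
#'
#' Regresses each feature's intensity on the sample run order by ordinary
#' least squares and tests the slope against zero (two-sided t). A nonzero
#' slope indicates carry-over or instrument drift across the acquisition
#' sequence. Features are flagged at the nominal type-I-error levels 0.05 and
#' 0.01.
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param order_col design column with the (numeric) run order.
#' @return list with `results` (per-feature data.frame: slope, intercept,
#'   r_squared, p_value) and `flags` (a `flag_table` with `flag_slope_05`,
#'   `flag_slope_01`, `flag_poor_data`).
#' @export
run_order_regression <- function(wide, design, order_col = "run_order") {
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  ord <- design_column(design, order_col)
  if (!is.numeric(ord)) stop_mf("run-order column '%s' must be numeric", order_col)
  if (length(unique(ord[!is.na(ord)])) < 3)
    stop_mf("run order needs at least 3 distinct values")
  v <- wide$values
  nf <- nrow(v)

  slope <- intercept <- r2 <- pval <- rep(NA_real_, nf)
  poor <- integer(nf)
  for (i in seq_len(nf)) {
    y <- v[i, ]
    keep <- !is.na(y) & !is.na(ord)
    x <- ord[keep]; yy <- y[keep]
    n <- length(yy)
    if (n < 3 || length(unique(x)) < 2) { poor[i] <- 1L; next }
    mx <- mean(x); my <- mean(yy)
    sxx <- sum((x - mx)^2)
    sxy <- sum((x - mx) * (yy - my))
    b1 <- sxy / sxx
    b0 <- my - b1 * mx
    res <- yy - (b0 + b1 * x)
    rss <- sum(res^2)
    tss <- sum((yy - my)^2)
    se <- sqrt(rss / (n - 2) / sxx)
    slope[i] <- b1; intercept[i] <- b0
    r2[i] <- if (tss > 0) 1 - rss / tss else 0
    if (se == 0 || !is.finite(se)) {
      # zero residual variance: constant feature (slope 0, no evidence) or a
      # perfect linear trend (overwhelming evidence)
      pval[i] <- if (b1 == 0) 1 else 0
    } else {
      pval[i] <- 2 * stats::pt(-abs(b1 / se), df = n - 2)
    }
  }

  flags <- flag_table(rownames(v), data.frame(
    flag_slope_05 = as.integer(!is.na(pval) & pval < 0.05),
    flag_slope_01 = as.integer(!is.na(pval) & pval < 0.01),
    flag_poor_data = poor))
  mf_log("ROR: ", sum(flags$flag_slope_05), " flagged at 0.05, ",
         sum(flags$flag_slope_01), " at 0.01, ",
         sum(poor), " skipped for poor data")
  list(results = data.frame(featureID = rownames(v), slope = slope,
                            intercept = intercept, r_squared = r2,
                            p_value = pval, row.names = NULL),
       flags = flags)
}

#' Regression plot for a single feature against run order
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param feature feature ID to plot.
#' @param order_col design column with the run order.
#' @param group_col optional design column used for point colors.
#' @return a ggplot object.
#' @export
ror_plot <- function(wide, design, feature, order_col = "run_order",
                     group_col = NULL) {
  al <- align_tables(wide, design)
  if (!feature %in% feature_ids(al$wide)) stop_mf("unknown feature '%s'", feature)
  df <- data.frame(order = design_column(al$design, order_col),
                   intensity = al$wide$values[feature, ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = order, y = intensity)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "grey40") +
    ggplot2::labs(title = feature, x = "run order", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(group_col)) {
    df$group <- design_groups(al$design, group_col)
    p <- p + ggplot2::geom_point(data = df, ggplot2::aes(color = group)) +
      ggplot2::scale_color_manual(values = group_colors(df$group))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p
}
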