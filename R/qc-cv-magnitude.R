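#' Coefficient-of-variation flags
#'
#' Per-feature CV = sd / mean, either overall or within each group. Features
#' with CV at or above the `(100 - percentile)`-th percentile of the CV
#' distribution are flagged (the top `percentile` percent; ties at the
#' boundary are all included, so the count can exceed the nominal number).
#' Features with zero mean have an undefined CV and receive a dedicated
#' `flag_cv_undefined` column.
#'
#' @param wide a `feature_table`.
#' @param design optional `design_table` (required when `by_group`).
#' @param group_col design column holding group labels.
#' @param percentile percent of features to flag (default 10).
#' @param by_group flag within each group separately (one column per group).
#' @return a `flag_table` over features; CV values attached as attribute
#'   `metrics`.
#' @export
cv_flags <- function(wide, design = NULL, group_col = "group",
                     percentile = 10, by_group = FALSE) {
  if (percentile < 0 || percentile > 100)
    stop_mf("percentile must be in [0, 100]")
  if (by_group && is.null(design))
    stop_mf("by_group = TRUE requires a design table")
  if (!is.null(design)) {
    al <- align_tables(wide, design)
    wide <- al$wide; design <- al$design
  }
  v <- wide$values

  cv_of <- function(m) {
    mu <- rowMeans(m, na.rm = TRUE)
    cv <- row_sds(m) / mu
    cv[!is.na(mu) & mu == 0] <- NA_real_
    cv
  }
  flag_top <- function(cv) {
    ok <- !is.na(cv)
    if (!any(ok)) return(integer(length(cv)))
    cut <- stats::quantile(cv[ok], 1 - percentile / 100, names = FALSE)
    as.integer(ok & cv >= cut)
  }

  if (by_group) {
    grp <- design_groups(design, group_col)
    cvs <- lapply(unique(grp), function(g) cv_of(v[, grp == g, drop = FALSE]))
    names(cvs) <- unique(grp)
    flags <- lapply(cvs, flag_top)
    names(flags) <- paste0("flag_cv_", names(cvs))
    flags <- as.data.frame(flags, optional = TRUE)
    undef <- as.integer(Reduce(`|`, lapply(cvs, is.na)))
    metrics <- as.data.frame(cvs, optional = TRUE)
  } else {
    cv <- cv_of(v)
    flags <- data.frame(flag_cv = flag_top(cv))
    undef <- as.integer(is.na(cv))
    metrics <- data.frame(cv = cv)
  }
  if (any(undef == 1))
    mf_log(sum(undef), " feature(s) with undefined CV (zero mean)", level = "WARN")
  flags$flag_cv_undefined <- undef
  out <- flag_table(rownames(v), flags)
  attr(out, "metrics") <- cbind(data.frame(featureID = rownames(v)), metrics)
  mf_log("CV flags: ", sum(rowSums(as.data.frame(out)[-1]) > 0), " of ",
         nrow(v), " features flagged")
  out
}

# digits before the decimal point of |v|: 0 for |v| < 1, NA for missing
digit_count <- function(v) {
  d <- rep(NA_real_, length(v))
  obs <- !is.na(v)
  av <- abs(v[obs])
  d[obs] <- ifelse(av < 1, 0, nchar(sprintf("%.0f", trunc(av))))
  d
}

#' Magnitude-difference flags
#'
#' Counts the digits before the decimal point of every intensity and looks,
#' within each group, at the per-feature spread (max - min) of digit counts
#' across samples. Features whose spread reaches `digit_gap` in any group are
#' flagged: intensities of a feature within a treatment group are expected to
#' share an order of magnitude, and wide spreads point at chromatographic or
#' sample-level artifacts. The report lists the `top_n` features with the
#' largest spread; per sample, the number of features whose digit count
#' departs from the group's modal count is tallied.
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param group_col design column holding group labels.
#' @param top_n number of features in the report (default 50).
#' @param digit_gap digit-count spread at which a feature is flagged.
#' @return list with `feature_flags` (flag_table: `flag_magnitude`), `report`
#'   (top features by digit spread, at most `top_n` rows), and
#'   `sample_counts` (data.frame of per-sample deviating-feature counts).
#' @export
magnitude_difference <- function(wide, design, group_col = "group",
                                 top_n = 50, digit_gap = 2) {
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  v <- wide$values
  digits <- matrix(digit_count(v), nrow = nrow(v), dimnames = dimnames(v))

  groups <- unique(grp)
  ranges <- sapply(groups, function(g) {
    sub <- digits[, grp == g, drop = FALSE]
    apply(sub, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) < 1) return(NA_real_)
      max(r) - min(r)
    })
  })
  if (is.null(dim(ranges))) ranges <- matrix(ranges, ncol = length(groups))
  max_range <- apply(ranges, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  flagged <- as.integer(!is.na(max_range) & max_range >= digit_gap)

  ord <- order(-replace(max_range, is.na(max_range), -Inf))
  qualifying <- ord[!is.na(max_range[ord]) & max_range[ord] > 0]
  report <- data.frame(featureID = rownames(v)[qualifying],
                       max_digit_range = max_range[qualifying],
                       row.names = NULL)
  report <- utils::head(report, top_n)

  # per sample: count of features whose digit count differs from the group mode
  modal <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    tx <- table(x)
    as.numeric(names(tx)[which.max(tx)])
  }
  deviates <- matrix(0L, nrow = nrow(v), ncol = ncol(v), dimnames = dimnames(v))
  for (g in groups) {
    cols <- which(grp == g)
    modes <- apply(digits[, cols, drop = FALSE], 1, modal)
    dv <- digits[, cols, drop = FALSE] != modes
    dv[is.na(dv)] <- FALSE
    deviates[, cols] <- dv + 0L
  }
  sample_counts <- data.frame(sampleID = colnames(v),
                              n_deviating = colSums(deviates),
                              row.names = NULL)
  mf_log("magnitude difference: ", sum(flagged), " feature(s) flagged at gap >= ",
         digit_gap)
  list(feature_flags = flag_table(rownames(v),
                                  data.frame(flag_magnitude = flagged)),
       report = report,
       sample_counts = sample_counts)
}

#' Per-sample magnitude-deviation plot
#' @param magnitude result of [magnitude_difference()].
#' @return a ggplot object showing deviating-feature counts per sample.
#' @export
magnitude_plot <- function(magnitude) {
  df <- magnitude$sample_counts
  df$sampleID <- factor(df$sampleID, levels = df$sampleID)
  ggplot2::ggplot(df, ggplot2::aes(x = sampleID, y = n_deviating)) +
    ggplot2::geom_col(fill = mf_palette(1)) +
    ggplot2::labs(x = NULL, y = "features deviating from group modal magnitude") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
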