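#' Normalization and re-scaling
#'
#' Two independent steps, applied in order. First an optional per-sample
#' factor: every sample's intensities are divided by that sample's mean,
#' median or sum over features. Second a per-feature scaling with feature mean
#' `m` and sample standard deviation `s` (n-1 denominator):
#' \describe{
#'   \item{center}{`x - m`}
#'   \item{autoscale}{`(x - m) / s`}
#'   \item{pareto}{`(x - m) / sqrt(s)`}
#'   \item{range}{`(x - m) / (max - min)`}
#'   \item{level}{`(x - m) / m`}
#'   \item{vast}{`((x - m) / s) * (m / s)`}
#' }
#' Missing values propagate. Degenerate features (zero `s`, zero range or
#' zero `m` where the method divides by it) and zero sample factors are not
#' errors: the affected outputs are set missing and reported via the log and
#' the `degenerate` attribute.
#'
#' @param wide a `feature_table`.
#' @param method per-feature scaling, or `"none"`.
#' @param sample_factor per-sample normalization factor.
#' @return a `feature_table` with scaled values; attribute `degenerate` lists
#'   features set missing.
#' @export
scale_features <- function(wide,
                           method = c("center", "autoscale", "pareto",
                                      "range", "level", "vast", "none"),
                           sample_factor = c("none", "mean", "median", "sum")) {
  method <- match.arg(method)
  sample_factor <- match.arg(sample_factor)
  v <- wide$values

  if (sample_factor != "none") {
    f <- switch(sample_factor,
                mean = colMeans(v, na.rm = TRUE),
                median = apply(v, 2, stats::median, na.rm = TRUE),
                sum = colSums(v, na.rm = TRUE))
    zero <- !is.na(f) & f == 0
    if (any(zero)) {
      mf_log("zero ", sample_factor, " factor for sample(s) ",
             paste(colnames(v)[zero], collapse = ", "),
             "; values set missing", level = "WARN")
      f[zero] <- NA_real_
    }
    v <- sweep(v, 2, f, "/")
  }

  degenerate <- character()
  if (method != "none") {
    m <- rowMeans(v, na.rm = TRUE)
    s <- row_sds(v)
    centered <- v - m
    v <- switch(method,
      center = centered,
      autoscale = centered / s,
      pareto = centered / sqrt(s),
      range = {
        rng <- apply(v, 1, function(r) diff(range(r, na.rm = TRUE)))
        centered / rng
      },
      level = centered / m,
      vast = (centered / s) * (m / s))
    bad <- !is.finite(rowSums(v, na.rm = TRUE)) |
      apply(v, 1, function(r) any(is.infinite(r) | is.nan(r)))
    if (any(bad)) {
      degenerate <- rownames(v)[bad]
      v[bad, ] <- NA_real_
      mf_log("scaling '", method, "' undefined for feature(s) ",
             paste(degenerate, collapse = ", "), "; set missing",
             level = "WARN")
    }
  }

  out <- feature_table(v, annotations = wide$annotations)
  attr(out, "degenerate") <- degenerate
  out
}

#' Log and generalized-log (g-log) transformation
#'
#' Computes `glog(x) = log_base((x + sqrt(x^2 + lambda)) / 2)`. With
#' `lambda = 0` this reduces exactly to the plain logarithm, which is the
#' default; a positive `lambda` (in squared-intensity units) keeps the
#' transform defined at zero and stabilizes the variance of low intensities.
#'
#' @param wide a `feature_table`.
#' @param base `2`, `10` or `"e"`.
#' @param glog_lambda g-log offset `lambda >= 0`; `0` requests a plain log.
#' @return a `feature_table` of transformed values.
#' @export
log_transform <- function(wide, base = 2, glog_lambda = 0) {
  if (identical(base, "e")) base <- exp(1)
  base <- as.numeric(base)
  if (!is.finite(base) || base <= 1) stop_mf("log base must be > 1 (or \"e\")")
  if (glog_lambda < 0) stop_mf("glog_lambda must be >= 0")
  v <- wide$values
  if (glog_lambda == 0) {
    bad <- rowSums(v <= 0, na.rm = TRUE) > 0
    if (any(bad))
      stop_mf("log with lambda = 0 requires strictly positive values; offending feature(s): %s",
              paste(utils::head(rownames(v)[bad], 10), collapse = ", "))
  }
  out <- log((v + sqrt(v^2 + glog_lambda)) / 2) / log(base)
  feature_table(out, annotations = wide$annotations)
}
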