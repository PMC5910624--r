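#' Impute missing intensities
#'
#' All methods operate within the treatment group of each sample, so group
#' structure is never blurred by imputation:
#' \describe{
#'   \item{group_mean / group_median}{replace a missing cell by the group
#'     statistic of its feature (deterministic).}
#'   \item{knn}{for each sample with a missing feature, the k nearest samples
#'     of the same group — Euclidean distance over co-observed features,
#'     neighbors must observe the feature — contribute their unweighted mean.}
#'   \item{stochastic_normal}{fit Normal(mu, sd) per feature per group from
#'     observed values and draw, truncated at 0; seeded.}
#'   \item{stochastic_poisson}{fit a Poisson rate to rounded observed values
#'     and draw; seeded. Intended for count-like intensities.}
#' }
#' Observed cells are never altered. Features with no observed value in a
#' group cannot be imputed there; they are left missing and reported.
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param method imputation method.
#' @param group_col design column holding group labels.
#' @param k neighbor count for `knn`; reduced with a warning when it reaches
#'   the group size.
#' @param seed RNG seed for the stochastic methods.
#' @return a `feature_table` with missing cells filled where possible.
#' @export
impute <- function(wide, design,
                   method = c("group_mean", "group_median", "knn",
                              "stochastic_normal", "stochastic_poisson"),
                   group_col = "group", k = 5, seed = 1) {
  method <- match.arg(method)
  if (k < 1) stop_mf("k must be >= 1")
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  v <- wide$values

  fill <- function(v) {
    for (g in unique(grp)) {
      cols <- which(grp == g)
      sub <- v[, cols, drop = FALSE]
      if (!anyNA(sub)) next
      v[, cols] <- impute_group(sub, method, k, g)
    }
    v
  }
  out <- if (startsWith(method, "stochastic")) {
    withr::with_seed(seed, fill(v))
  } else fill(v)

  left <- sum(is.na(out)) - 0L
  if (left > 0)
    mf_log(left, " cell(s) could not be imputed (no observed values in group)",
           level = "WARN")
  feature_table(out, annotations = wide$annotations)
}

impute_group <- function(sub, method, k, gname) {
  obs_per_feature <- rowSums(!is.na(sub))
  none <- obs_per_feature == 0 & rowSums(is.na(sub)) > 0
  if (any(none))
    mf_log("group ", gname, ": ", sum(none),
           " feature(s) unobserved, left missing", level = "WARN")

  if (method %in% c("group_mean", "group_median")) {
    stat <- if (method == "group_mean") rowMeans(sub, na.rm = TRUE)
            else apply(sub, 1, stats::median, na.rm = TRUE)
    idx <- which(is.na(sub), arr.ind = TRUE)
    repl <- stat[idx[, 1]]
    keep <- is.finite(repl)
    sub[idx[keep, , drop = FALSE]] <- repl[keep]
    return(sub)
  }

  if (method == "knn") {
    n <- ncol(sub)
    if (k >= n) {
      mf_log("knn: k = ", k, " >= group size ", n, " in group ", gname,
             ", reduced to ", n - 1L, level = "WARN")
      k <- max(1L, n - 1L)
    }
    filled <- sub
    for (j in seq_len(n)) {
      miss_f <- which(is.na(sub[, j]))
      if (!length(miss_f)) next
      others <- setdiff(seq_len(n), j)
      # distance on co-observed features, scaled to per-feature RMS so that
      # varying overlap sizes stay comparable
      d <- vapply(others, function(o) {
        co <- !is.na(sub[, j]) & !is.na(sub[, o])
        if (!any(co)) return(Inf)
        sqrt(mean((sub[co, j] - sub[co, o])^2))
      }, numeric(1))
      for (f in miss_f) {
        cand <- others[!is.na(sub[f, others]) & is.finite(d)]
        if (!length(cand)) next
        ord <- cand[order(d[match(cand, others)])]
        nb <- utils::head(ord, k)
        filled[f, j] <- mean(sub[f, nb])
      }
    }
    return(filled)
  }

  # stochastic methods: per-feature fits from observed values
  for (f in which(obs_per_feature > 0)) {
    miss <- which(is.na(sub[f, ]))
    if (!length(miss)) next
    x <- sub[f, !is.na(sub[f, ])]
    if (method == "stochastic_normal") {
      mu <- mean(x)
      sdev <- if (length(x) > 1) stats::sd(x) else 0
      if (sdev == 0) {
        sub[f, miss] <- mu
      } else {
        # truncated-at-zero Normal via inverse-CDF so no rejection loop
        lo <- stats::pnorm(0, mu, sdev)
        u <- stats::runif(length(miss), lo, 1)
        sub[f, miss] <- stats::qnorm(u, mu, sdev)
      }
    } else {
      lambda <- mean(round(x))
      if (lambda < 0) lambda <- 0
      sub[f, miss] <- stats::rpois(length(miss), lambda)
    }
  }
  sub
}
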