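# Sample-distance QC: standardized Euclidean distance (SED) and penalized
# Mahalanobis distance (PMD). Both compare each sample to its group center
# (the per-feature mean over the group) and to every other sample of the
# group, and flag samples whose squared distance to the center exceeds
# chi-square quantiles.

.sed_levels <- c(0.95, 0.975, 0.99)

# per-group feature screening shared by sed/pmd: drop features with missing
# values or zero variance within the group
screen_group_features <- function(sub, gname) {
  has_na <- rowSums(is.na(sub)) > 0
  if (any(has_na))
    mf_log("group ", gname, ": ", sum(has_na),
           " feature(s) with missing values excluded from distances")
  keep <- !has_na
  v <- rep(NA_real_, nrow(sub))
  v[keep] <- apply(sub[keep, , drop = FALSE], 1, stats::var)
  zero <- keep & v == 0
  if (any(zero))
    mf_log("group ", gname, ": ", sum(zero),
           " zero-variance feature(s) excluded from distances")
  list(keep = keep & !zero, zero_variance = rownames(sub)[zero],
       missing = rownames(sub)[has_na])
}

distance_result <- function(per_group, sids, method) {
  to_center2 <- unlist(lapply(per_group, function(g) g$to_center^2))
  flags <- data.frame(row.names = seq_along(sids))
  for (lv in .sed_levels) {
    f <- rep(NA_integer_, length(sids))
    for (g in per_group) {
      cut <- g$cutoffs[[as.character(lv)]]
      f[match(names(g$to_center), sids)] <- as.integer(g$to_center^2 > cut)
    }
    flags[[sprintf("flag_outlier_%g", lv * 100)]] <- f
  }
  structure(list(per_group = per_group,
                 flags = flag_table(sids, flags, id_col = "sampleID"),
                 method = method),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> method = %s | groups: %s\n", x$method,
              paste(names(x$per_group), collapse = ", ")))
  for (g in names(x$per_group))
    cat(sprintf("  %s: %d samples, %d features used\n", g,
                length(x$per_group[[g]]$to_center),
                x$per_group[[g]]$n_features_used))
  invisible(x)
}

#' Standardized Euclidean distance (SED) to group center and between samples
#'
#' Within each group the center `y` is the per-feature mean over the group's
#' samples and `sigma_i^2` the per-feature sample variance; the distance of a
#' sample `x` is `SED(x, y) = sqrt(sum_i (x_i - y_i)^2 / sigma_i^2)`.
#' Pairwise SEDs between group members use the same per-feature variances.
#' Squared distances to the center are compared with chi-square quantiles
#' (df = number of features used) at confidence levels 0.95 / 0.975 / 0.99 to
#' flag potentially aberrant samples. Features with missing values or zero
#' variance within a group are excluded from that group's sums (logged);
#' singleton groups are skipped with a warning.
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param group_col design column holding group labels.
#' @return a `distance_result`: per group `to_center` (named vector),
#'   `pairwise` (symmetric matrix, zero diagonal), `cutoffs` (on the squared
#'   distance), `n_features_used`, `excluded`; plus `flags`, a sample-level
#'   `flag_table` at the three confidence levels.
#' @export
sed <- function(wide, design, group_col = "group") {
  compute_group_distances(wide, design, group_col, method = "sed")
}

#' Penalized Mahalanobis distance (PMD)
#'
#' The Mahalanobis distance `MD(x, y) = sqrt((x - y)' Sigma^{-1} (x - y))`
#' generalizes the SED by accounting for between-feature covariance. With
#' more features than samples the sample covariance `S` is singular, so a
#' penalized estimate is used: `Sigma(rho) = (1 - rho) S + rho diag(S)`,
#' shrinking toward the diagonal. At `rho = 1` (or when `S` is diagonal) the
#' PMD is exactly the SED. Output format and outlier cutoffs are identical to
#' [sed()].
#'
#' @inheritParams sed
#' @param shrinkage shrinkage weight `rho` in `[0, 1]`, or `"auto"`: the
#'   smallest value on the grid 0.01, 0.02, ..., 1 whose penalized matrix has
#'   condition number at most 1e6.
#' @return a `distance_result`; each group additionally records the `rho`
#'   used.
#' @export
pmd <- function(wide, design, group_col = "group", shrinkage = "auto") {
  if (!identical(shrinkage, "auto")) {
    shrinkage <- as.numeric(shrinkage)
    if (is.na(shrinkage) || shrinkage < 0 || shrinkage > 1)
      stop_mf("shrinkage must be in [0, 1] or \"auto\"")
  }
  compute_group_distances(wide, design, group_col, method = "pmd",
                          shrinkage = shrinkage)
}

compute_group_distances <- function(wide, design, group_col, method,
                                    shrinkage = NULL) {
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  sids <- sample_ids(wide)
  per_group <- list()

  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) < 2) {
      mf_log("group ", g, " has a single sample; skipped", level = "WARN")
      next
    }
    sub <- wide$values[, cols, drop = FALSE]
    sc <- screen_group_features(sub, g)
    sub <- sub[sc$keep, , drop = FALSE]
    if (nrow(sub) == 0) {
      if (method == "pmd")
        stop_mf("group %s has no usable (non-constant) features", g)
      mf_log("group ", g, ": no usable features, skipped", level = "WARN")
      next
    }
    center <- rowMeans(sub)
    p <- nrow(sub); n <- ncol(sub)
    rho_used <- NA_real_

    if (method == "sed") {
      s2 <- apply(sub, 1, stats::var)
      qf <- function(dvec) sum(dvec^2 / s2)
    } else {
      S <- stats::cov(t(sub))
      rho_used <- if (identical(shrinkage, "auto")) auto_rho(S) else shrinkage
      Sig <- (1 - rho_used) * S + rho_used * diag(diag(S), nrow = p)
      Sinv <- tryCatch(chol2inv(chol(Sig)), error = function(e)
        stop_mf("penalized covariance for group %s is not invertible (rho = %g)",
                g, rho_used))
      qf <- function(dvec) drop(crossprod(dvec, Sinv %*% dvec))
    }

    to_center <- sqrt(apply(sub - center, 2, qf))
    pairwise <- matrix(0, n, n, dimnames = list(colnames(sub), colnames(sub)))
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      dd <- sqrt(qf(sub[, i] - sub[, j]))
      pairwise[i, j] <- dd; pairwise[j, i] <- dd
    }
    cutoffs <- stats::setNames(stats::qchisq(.sed_levels, df = p),
                               as.character(.sed_levels))
    per_group[[g]] <- list(to_center = to_center, pairwise = pairwise,
                           cutoffs = cutoffs, n_features_used = p,
                           rho = rho_used,
                           excluded = list(missing = sc$missing,
                                           zero_variance = sc$zero_variance))
  }
  if (!length(per_group)) stop_mf("no group with >= 2 samples")
  distance_result(per_group, sids, method)
}

# smallest rho on a 0.01 grid keeping the penalized covariance well
# conditioned (ratio of extreme eigenvalues <= 1e6)
auto_rho <- function(S, max_condition = 1e6) {
  dS <- diag(diag(S), nrow = nrow(S))
  for (rho in seq(0.01, 1, by = 0.01)) {
    ev <- eigen((1 - rho) * S + rho * dS, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) <= max_condition) return(rho)
  }
  1
}

#' Box-and-whisker summary of sample distances
#' @param dist a `distance_result` from [sed()] or [pmd()].
#' @return a ggplot object of distances to the group center, by group.
#' @export
distance_plot <- function(dist) {
  df <- do.call(rbind, lapply(names(dist$per_group), function(g)
    data.frame(group = g,
               sampleID = names(dist$per_group[[g]]$to_center),
               distance = unname(dist$per_group[[g]]$to_center))))
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = distance, fill = group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::scale_fill_manual(values = group_colors(df$group)) +
    ggplot2::labs(y = paste(toupper(dist$method), "to group center"), x = NULL) +
    ggplot2::theme_minimal()
}
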