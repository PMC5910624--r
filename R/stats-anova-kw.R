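#' Fixed-effects ANOVA per feature
#'
#' Fits, for every feature, the least-squares model of intensity on one or
#' more categorical factors plus optional numeric covariates, under the
#' standard assumption of normal i.i.d. errors. With `interaction = TRUE` and
#' at least two factors, all factor-by-factor interactions are included.
#' Per-feature output is: the F-test per model term (sequential ANOVA table),
#' all pairwise contrasts of the primary factor (the first in `factors`) with
#' t-based p-values computed on the pooled residual mean square, and residual
#' diagnostics (MSE, residual df). Contrast estimates are differences of
#' adjusted group means (raw group-mean differences when no covariates are
#' present), and feed the volcano plot.
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param factors character vector of categorical design columns; the first
#'   is the primary factor whose pairwise contrasts are reported.
#' @param covariates character vector of numeric design columns.
#' @param interaction include factor interactions (needs >= 2 factors).
#' @return list with `contrasts` (long data.frame: featureID, contrast,
#'   estimate, statistic, df, p_value, flags), `factors` (featureID, term, F,
#'   p_value) and `diagnostics` (featureID, mse, df_residual).
#' @export
anova_fixed <- function(wide, design, factors, covariates = character(),
                        interaction = FALSE) {
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  if (length(factors) < 1) stop_mf("at least one categorical factor required")
  if (interaction && length(factors) < 2)
    stop_mf("interaction requires at least two factors")
  for (cn in c(factors, covariates)) design_column(design, cn)  # existence

  df0 <- design$data
  for (f in factors) df0[[f]] <- factor(df0[[f]])
  for (cv in covariates) {
    if (!is.numeric(df0[[cv]])) stop_mf("covariate '%s' must be numeric", cv)
  }
  op <- if (interaction) " * " else " + "
  rhs <- paste(c(paste(factors, collapse = op), covariates), collapse = " + ")
  form <- stats::as.formula(paste("..y ~", rhs))

  primary <- factors[1]
  lev <- levels(df0[[primary]])
  pairs <- if (length(lev) >= 2) utils::combn(lev, 2) else
    stop_mf("primary factor '%s' needs >= 2 levels", primary)

  v <- wide$values
  contr_rows <- vector("list", nrow(v))
  factor_rows <- vector("list", nrow(v))
  diag_rows <- vector("list", nrow(v))

  for (i in seq_len(nrow(v))) {
    dat <- df0
    dat$..y <- v[i, ]
    dat <- dat[!is.na(dat$..y), , drop = FALSE]
    fid <- rownames(v)[i]
    if (nrow(dat) <= length(c(factors, covariates)) + 1) {
      mf_log("feature ", fid, ": too few observations for the model, skipped",
             level = "WARN")
      next
    }
    fit <- stats::lm(form, data = dat)
    X <- stats::model.matrix(fit)
    if (fit$rank < ncol(X)) {
      aliased <- names(which(is.na(stats::coef(fit))))
      stop_mf("rank-deficient model for feature %s; aliased terms: %s",
              fid, paste(aliased, collapse = ", "))
    }
    an <- stats::anova(fit)
    terms_tab <- an[rownames(an) != "Residuals", , drop = FALSE]
    factor_rows[[i]] <- data.frame(featureID = fid,
                                   term = rownames(terms_tab),
                                   F = terms_tab[["F value"]],
                                   p_value = terms_tab[["Pr(>F)"]],
                                   row.names = NULL)
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    diag_rows[[i]] <- data.frame(featureID = fid, mse = mse,
                                 df_residual = fit$df.residual)

    Vc <- stats::vcov(fit)
    cf <- stats::coef(fit)
    cn <- names(cf)
    contr_rows[[i]] <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      # contrast on the treatment-coded coefficients: level effect is 0 for
      # the reference level, the dummy coefficient otherwise
      w <- stats::setNames(rep(0, length(cf)), cn)
      ca <- paste0(primary, a); cb <- paste0(primary, b)
      if (ca %in% cn) w[ca] <- w[ca] + 1
      if (cb %in% cn) w[cb] <- w[cb] - 1
      est <- sum(w * cf)
      se <- sqrt(drop(t(w) %*% Vc %*% w))
      tval <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
      pval <- if (se > 0) 2 * stats::pt(-abs(tval), df = fit$df.residual) else
        ifelse(est == 0, 1, 0)
      data.frame(featureID = fid, contrast = paste(a, "-", b),
                 estimate = est, statistic = tval,
                 df = fit$df.residual, p_value = pval, row.names = NULL)
    }))
  }

  contrasts <- add_sig_flags(do.call(rbind, contr_rows))
  list(contrasts = contrasts,
       factors = do.call(rbind, factor_rows),
       diagnostics = do.call(rbind, diag_rows))
}

#' Kruskal-Wallis test per feature
#'
#' Rank-based nonparametric comparison of two or more groups, computed with
#' midranks and the standard tie correction; the statistic H is referred to a
#' chi-square distribution with k - 1 df. Takes the same inputs as the ANOVA
#' tool. Pairwise "estimates" for the volcano output are differences of group
#' medians; the p-value attached to every contrast of a feature is the
#' feature's overall Kruskal-Wallis p.
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param group_col design column holding group labels.
#' @return list with `results` (featureID, H, df, p_value, flags) and
#'   `contrasts` (featureID, contrast, estimate = median difference,
#'   p_value).
#' @export
kruskal_wallis <- function(wide, design, group_col = "group") {
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  lev <- unique(grp)
  if (length(lev) < 2) stop_mf("Kruskal-Wallis requires >= 2 groups")
  if (any(table(grp) < 2)) stop_mf("each group needs at least 2 samples")
  pairs <- utils::combn(lev, 2)
  v <- wide$values

  res <- lapply(seq_len(nrow(v)), function(i) {
    y <- v[i, ]
    keep <- !is.na(y)
    g <- factor(grp[keep])
    if (length(unique(g)) < 2 || length(y[keep]) < 3)
      return(list(H = NA_real_, df = NA_real_, p = NA_real_, med = NULL))
    yk <- y[keep]
    if (length(unique(yk)) == 1) {
      # all observations tied: no rank information at all
      H <- 0; p <- 1; dfk <- length(unique(g)) - 1
    } else {
      kt <- stats::kruskal.test(yk, g)
      H <- unname(kt$statistic); p <- kt$p.value; dfk <- unname(kt$parameter)
    }
    med <- tapply(yk, as.character(g), stats::median)
    list(H = H, df = dfk, p = p, med = med)
  })

  results <- data.frame(featureID = rownames(v),
                        H = vapply(res, `[[`, numeric(1), "H"),
                        df = vapply(res, `[[`, numeric(1), "df"),
                        p_value = vapply(res, `[[`, numeric(1), "p"),
                        row.names = NULL)
  results <- add_sig_flags(results)

  contrasts <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
    med <- res[[i]]$med
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      est <- if (!is.null(med) && all(c(a, b) %in% names(med)))
        unname(med[a] - med[b]) else NA_real_
      data.frame(featureID = rownames(v)[i], contrast = paste(a, "-", b),
                 estimate = est, p_value = res[[i]]$p, row.names = NULL)
    }))
  }))
  list(results = results, contrasts = contrasts)
}
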