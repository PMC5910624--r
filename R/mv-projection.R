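# Projection methods: PCA (SVD), PLS-DA (NIPALS, binary response), LDA.
# Samples are rows in all score matrices; features are rows in
# loadings/weights, matching the wide-format orientation.

check_no_missing <- function(wide, tool) {
  if (anyNA(wide$values))
    stop_mf("%s requires complete data: impute or drop missing values first", tool)
}

# autoscale a samples x features matrix, dropping zero-variance columns
autoscale_cols <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  keep <- s > 0
  if (!all(keep))
    mf_log(sum(!keep), " constant feature(s) dropped before scaling", level = "WARN")
  X <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  attr(X, "kept") <- keep
  X
}

cv_gate <- function(cv, n) {
  if (!identical(cv, "none") && n <= 100)
    stop_mf("cross-validation is only supported for sample sizes larger than 100 (n = %d)", n)
}

#' Principal component analysis
#'
#' Column-centers the samples-by-features matrix and factors it by singular
#' value decomposition. Components are orthogonal and ordered by decreasing
#' explained variance.
#'
#' @param wide a `feature_table` without missing values.
#' @param design optional `design_table`; group labels are carried along for
#'   plotting.
#' @param group_col design column holding group labels.
#' @param n_comp number of components to keep (clamped to `min(n - 1, p)`).
#' @return list of class `projection_result`: `scores` (samples x
#'   components), `loadings` (features x components), `explained` (proportion
#'   of variance per kept component), `groups`.
#' @export
pca <- function(wide, design = NULL, group_col = "group", n_comp = NULL) {
  check_no_missing(wide, "PCA")
  groups <- NULL
  if (!is.null(design)) {
    al <- align_tables(wide, design)
    wide <- al$wide; design <- al$design
    groups <- design_groups(design, group_col)
  }
  X <- t(wide$values)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl_all <- pc$sdev^2 / sum(pc$sdev^2)
  k_max <- sum(pc$sdev > 0)
  k <- min(n_comp %||% k_max, k_max, nrow(X) - 1, ncol(X))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = expl_all[seq_len(k)],
                 explained_all = expl_all,
                 groups = groups, method = "pca"),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %s | %d samples x %d components\n",
              x$method, nrow(x$scores), ncol(x$scores)))
  if (!is.null(x$explained))
    cat("explained:", paste(sprintf("%.1f%%", 100 * x$explained), collapse = " "), "\n")
  invisible(x)
}

#' 2D scores plot of a projection
#' @param proj a `projection_result`.
#' @param comps two component indices.
#' @return a ggplot object colored by group.
#' @export
projection_plot <- function(proj, comps = c(1, 2)) {
  sc <- proj$scores
  if (max(comps) > ncol(sc)) stop_mf("component index out of range")
  df <- data.frame(x = sc[, comps[1]], y = sc[, comps[2]],
                   group = proj$groups %||% "all")
  lab <- function(i) {
    if (!is.null(proj$explained) && i <= length(proj$explained))
      sprintf("comp %d (%.1f%%)", i, 100 * proj$explained[i])
    else sprintf("comp %d", i)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, color = group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = group_colors(df$group)) +
    ggplot2::labs(x = lab(comps[1]), y = lab(comps[2]),
                  title = toupper(proj$method)) +
    ggplot2::theme_minimal()
}

#' 3D scores scatter of the first three components
#' @param proj a `projection_result` with at least 3 components.
#' @return a lattice cloud plot.
#' @export
projection_plot_3d <- function(proj) {
  sc <- proj$scores
  if (ncol(sc) < 3) stop_mf("3D plot needs at least 3 components")
  df <- data.frame(PC1 = sc[, 1], PC2 = sc[, 2], PC3 = sc[, 3],
                   group = factor(proj$groups %||% "all"))
  cols <- group_colors(df$group)
  lattice::cloud(PC3 ~ PC1 * PC2, data = df, groups = df$group,
                 par.settings = list(superpose.symbol = list(col = cols)),
                 auto.key = TRUE)
}

#' Partial least squares discriminant analysis (PLS-DA)
#'
#' PLS1 regression (NIPALS algorithm) of a binary group response on the
#' autoscaled feature matrix, used as a discriminant projection for exactly
#' two groups. Scores and weights per component are returned together with
#' training predictions (response threshold at the midpoint of the two coded
#' labels). Cross-validated selection of the component count is gated to
#' sample sizes above 100.
#'
#' @param wide a `feature_table` without missing values.
#' @param design a `design_table`.
#' @param group_col design column holding the two group labels.
#' @param n_comp number of latent components.
#' @param cv `"none"`, `"single"` (5-fold) or `"double"` (5 x 5 nested);
#'   selects `n_comp` by classification accuracy, only for n > 100.
#' @param scale autoscale features first (recommended; PLS is
#'   scale-sensitive).
#' @param seed RNG seed for CV folds.
#' @return list of class `projection_result` with `scores`, `weights`,
#'   `loadings`, `predicted`, `accuracy`, `groups`, and `n_comp`.
#' @export
plsda <- function(wide, design, group_col = "group", n_comp = 2,
                  cv = c("none", "single", "double"), scale = TRUE, seed = 1) {
  cv <- match.arg(cv)
  check_no_missing(wide, "PLS-DA")
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  lev <- sort(unique(grp))     # stable 0/1 coding regardless of design order
  if (length(lev) != 2)
    stop_mf("PLS-DA is applied to two groups, found %d", length(lev))
  n <- length(grp)
  cv_gate(cv, n)

  X <- t(wide$values)
  if (scale) X <- autoscale_cols(X) else attr(X, "kept") <- rep(TRUE, ncol(X))
  y <- as.numeric(grp == lev[2])        # 0/1 coding

  if (cv != "none") {
    accs <- vapply(seq_len(n_comp), function(k)
      plsda_cv_accuracy(X, y, k, nested = (cv == "double"), seed = seed),
      numeric(1))
    n_comp <- which.max(accs)
  }

  fit <- nipals_pls1(X, y - mean(y), n_comp)
  yhat <- mean(y) + drop(X %*% fit$coef)
  predicted <- ifelse(yhat >= 0.5, lev[2], lev[1])
  structure(list(scores = fit$scores, weights = fit$weights,
                 loadings = fit$loadings,
                 predicted = stats::setNames(predicted, rownames(X)),
                 accuracy = mean(predicted == grp),
                 explained = NULL, groups = grp, n_comp = n_comp,
                 kept_features = attr(X, "kept"), method = "plsda"),
            class = "projection_result")
}

# NIPALS PLS1: X (n x p, centered/scaled), y centered. Returns scores T,
# weights W, X-loadings P and the regression coefficients for y.
nipals_pls1 <- function(X, y, n_comp) {
  n <- nrow(X); p <- ncol(X)
  n_comp <- min(n_comp, n - 1, p)
  W <- matrix(0, p, n_comp); P <- matrix(0, p, n_comp)
  Tm <- matrix(0, n, n_comp); q <- numeric(n_comp)
  Xd <- X; yd <- y
  for (k in seq_len(n_comp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw == 0) { n_comp <- k - 1L; break }
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    pv <- drop(crossprod(Xd, tt)) / tt2
    qk <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pv)
    yd <- yd - tt * qk
    W[, k] <- w; P[, k] <- pv; Tm[, k] <- tt; q[k] <- qk
  }
  keep <- seq_len(max(n_comp, 1L))
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; q <- q[keep]
  # coefficients in original X space: B = W (P'W)^{-1} q
  B <- W %*% solve(crossprod(P, W), q)
  dimnames(Tm) <- list(rownames(X), paste0("comp", keep))
  dimnames(W) <- list(colnames(X), paste0("comp", keep))
  dimnames(P) <- dimnames(W)
  list(scores = Tm, weights = W, loadings = P, coef = drop(B))
}

plsda_cv_accuracy <- function(X, y, k, nested = FALSE, seed = 1, folds = 5) {
  withr::with_seed(seed, {
    n <- nrow(X)
    fold <- make_stratified_folds(y, folds)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      if (!any(te) || length(unique(y[tr])) < 2) next
      kk <- k
      if (nested) {
        inner <- make_stratified_folds(y[tr], folds)
        inner_acc <- vapply(seq_len(k), function(kc) {
          ok <- 0L
          for (g in seq_len(folds)) {
            itr <- inner != g
            if (length(unique(y[tr][itr])) < 2) next
            fit <- nipals_pls1(X[tr, , drop = FALSE][itr, , drop = FALSE],
                               y[tr][itr] - mean(y[tr][itr]), kc)
            pred <- mean(y[tr][itr]) +
              X[tr, , drop = FALSE][!itr, , drop = FALSE] %*% fit$coef
            ok <- ok + sum((pred >= 0.5) == (y[tr][!itr] == 1))
          }
          ok
        }, numeric(1))
        kk <- which.max(inner_acc)
      }
      fit <- nipals_pls1(X[tr, , drop = FALSE], y[tr] - mean(y[tr]), kk)
      pred <- mean(y[tr]) + X[te, , drop = FALSE] %*% fit$coef
      correct <- correct + sum((pred >= 0.5) == (y[te] == 1))
    }
    correct / n
  })
}

make_stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Linear discriminant analysis
#'
#' Projects samples onto the discriminant axes that maximize between-group
#' relative to within-group variance (at most `n_groups - 1` axes), assuming
#' per-group multivariate normality with a shared covariance. Backed by
#' [MASS::lda()]; features are autoscaled first by default. CV options follow
#' the same n > 100 gate as PLS-DA.
#'
#' @param wide a `feature_table` without missing values.
#' @param design a `design_table`.
#' @param group_col design column holding group labels.
#' @param n_comp number of discriminant axes (must be `< n_groups`).
#' @param cv `"none"`, `"single"` or `"double"` (n > 100 only); selects
#'   `n_comp` by classification accuracy.
#' @param scale autoscale features first.
#' @param seed RNG seed for CV folds.
#' @return list of class `projection_result` with `scores`, `loadings`
#'   (discriminant coefficients), `predicted`, `accuracy`, `groups`.
#' @export
lda_project <- function(wide, design, group_col = "group", n_comp = NULL,
                        cv = c("none", "single", "double"), scale = TRUE,
                        seed = 1) {
  cv <- match.arg(cv)
  check_no_missing(wide, "LDA")
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  k_groups <- length(unique(grp))
  if (k_groups < 2) stop_mf("LDA requires >= 2 groups")
  max_comp <- k_groups - 1
  n_comp <- n_comp %||% max_comp
  if (n_comp >= k_groups)
    stop_mf("the discriminant subspace dimension must be smaller than the number of groups (max %d)",
            max_comp)
  n <- length(grp)
  cv_gate(cv, n)

  X <- t(wide$values)
  if (scale) X <- autoscale_cols(X)
  fit <- suppressWarnings(MASS::lda(X, grouping = factor(grp)))
  pred <- stats::predict(fit)
  k <- min(n_comp, ncol(fit$scaling))
  structure(list(scores = pred$x[, seq_len(k), drop = FALSE],
                 loadings = fit$scaling[, seq_len(k), drop = FALSE],
                 predicted = stats::setNames(as.character(pred$class), rownames(X)),
                 accuracy = mean(as.character(pred$class) == grp),
                 explained = NULL, groups = grp, n_comp = k, method = "lda"),
            class = "projection_result")
}
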