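# Classifier / selection tools: random-forest importance, SVM prediction,
# LASSO / elastic-net feature selection.

#' Random-forest feature importance
#'
#' Grows an ensemble of decision trees on bootstrap samples with random
#' feature subsets and scores every feature by its mean decrease in Gini
#' impurity for the group-classification task, then rank-orders them.
#'
#' @param wide a `feature_table` without missing values.
#' @param design a `design_table`.
#' @param group_col design column holding group labels.
#' @param n_trees number of trees (default 1000).
#' @param seed RNG seed (fixed seed gives an identical ranking).
#' @param top_n number of features shown by [rf_importance_plot()].
#' @return list with `importance` (data.frame sorted by decreasing score:
#'   featureID, importance, rank), `model` (the randomForest fit), `top_n`.
#' @export
rf_importance <- function(wide, design, group_col = "group", n_trees = 1000,
                          seed = 1, top_n = 20) {
  check_no_missing(wide, "random forest")
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- factor(design_groups(design, group_col))
  if (nlevels(grp) < 2) stop_mf("random forest requires >= 2 groups")
  X <- t(wide$values)
  colnames(X) <- make.names(colnames(X))   # randomForest needs syntactic names
  fit <- withr::with_seed(seed,
    randomForest::randomForest(x = X, y = grp, ntree = n_trees,
                               importance = TRUE))
  imp <- randomForest::importance(fit, type = 2)[, 1]   # mean decrease Gini
  ord <- order(-imp)
  tab <- data.frame(featureID = feature_ids(wide)[ord],
                    importance = unname(imp[ord]),
                    rank = seq_along(imp), row.names = NULL)
  list(importance = tab, model = fit, top_n = top_n)
}

#' Variable-importance plot of the top features
#' @param rf result of [rf_importance()].
#' @return a ggplot object.
#' @export
rf_importance_plot <- function(rf) {
  df <- utils::head(rf$importance, rf$top_n)
  df$featureID <- factor(df$featureID, levels = rev(df$featureID))
  ggplot2::ggplot(df, ggplot2::aes(x = importance, y = featureID)) +
    ggplot2::geom_point(color = mf_palette(1)) +
    ggplot2::labs(x = "mean decrease in Gini impurity", y = NULL) +
    ggplot2::theme_minimal()
}

#' SVM classification of a target dataset
#'
#' Trains a support-vector machine on a labeled training feature table and
#' predicts the group of every sample in a target table sharing (a superset
#' of) the training features. Reports resubstitution accuracy on the training
#' set. Cross-validated selection of the cost parameter is gated to training
#' sizes above 100.
#'
#' @param wide_train,design_train training feature table and design.
#' @param group_col design column with known class labels.
#' @param wide_target feature table to classify (its features must include
#'   all training features).
#' @param kernel `"linear"`, `"rbf"` or `"poly"`.
#' @param C cost parameter.
#' @param cv `"none"` or `"single"`: 5-fold grid search over C (n > 100 only).
#' @param scale autoscale features (shared scaling from the training set).
#' @param seed RNG seed for CV folds.
#' @return list with `predictions` (named character vector over target
#'   samples), `training_accuracy`, `model`, `C`.
#' @export
svm_classify <- function(wide_train, design_train, group_col = "group",
                         wide_target = NULL,
                         kernel = c("linear", "rbf", "poly"), C = 1,
                         cv = c("none", "single"), scale = TRUE, seed = 1) {
  kernel <- match.arg(kernel)
  cv <- match.arg(cv)
  check_no_missing(wide_train, "SVM")
  al <- align_tables(wide_train, design_train)
  wide_train <- al$wide; design_train <- al$design
  grp <- factor(design_groups(design_train, group_col))
  X <- t(wide_train$values)
  cv_gate(cv, nrow(X))

  if (!is.null(wide_target)) {
    check_no_missing(wide_target, "SVM")
    missing_feats <- setdiff(feature_ids(wide_train), feature_ids(wide_target))
    if (length(missing_feats))
      stop_mf("target is missing training feature(s): %s",
              paste(utils::head(missing_feats, 10), collapse = ", "))
    Xt <- t(wide_target$values[feature_ids(wide_train), , drop = FALSE])
  }

  ekernel <- c(linear = "linear", rbf = "radial", poly = "polynomial")[[kernel]]
  if (cv == "single") {
    grid <- c(0.01, 0.1, 1, 10, 100)
    acc <- withr::with_seed(seed, vapply(grid, function(cc) {
      fold <- make_stratified_folds(as.integer(grp), 5)
      ok <- 0L
      for (f in 1:5) {
        tr <- fold != f
        m <- e1071::svm(X[tr, , drop = FALSE], grp[tr], kernel = ekernel,
                        cost = cc, scale = scale)
        ok <- ok + sum(stats::predict(m, X[!tr, , drop = FALSE]) == grp[!tr])
      }
      ok / nrow(X)
    }, numeric(1)))
    C <- grid[which.max(acc)]
  }

  model <- e1071::svm(X, grp, kernel = ekernel, cost = C, scale = scale)
  train_pred <- stats::predict(model, X)
  predictions <- if (!is.null(wide_target)) {
    pr <- stats::predict(model, Xt)
    stats::setNames(as.character(pr), rownames(Xt))
  } else NULL
  list(predictions = predictions,
       training_accuracy = mean(train_pred == grp),
       model = model, C = C)
}

#' LASSO / elastic-net feature selection
#'
#' For every unordered pair of groups, fits a penalized logistic regression
#' over a descending lambda path (100 values spanning 4 decades below the
#' all-zero-solution lambda) and picks lambda by cross-validated binomial
#' deviance. The selected set is the features with nonzero coefficients at
#' the chosen lambda. The mixing parameter `alpha` in `[0, 1]` interpolates
#' between ridge (`alpha = 0`: shrinkage only, every feature keeps a nonzero
#' coefficient) and LASSO (`alpha = 1`: sparsest selection); the default is
#' 0.5. Backed by glmnet; features are standardized internally.
#'
#' @param wide a `feature_table` without missing values.
#' @param design a `design_table`.
#' @param group_col design column holding group labels.
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param n_lambda lambda-path length.
#' @param cv_folds cross-validation folds for the lambda choice.
#' @param seed RNG seed (fold assignment).
#' @return list of class `selection_result`, one element per group pair:
#'   `selected` (feature IDs), `coefficients` (named vector at the chosen
#'   lambda), `lambda`, `alpha`, `fit` (the cv.glmnet object).
#' @export
elastic_net_select <- function(wide, design, group_col = "group", alpha = 0.5,
                               n_lambda = 100, cv_folds = 5, seed = 1) {
  if (alpha < 0 || alpha > 1) stop_mf("alpha must be in [0, 1]")
  check_no_missing(wide, "elastic net")
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  lev <- unique(grp)
  if (length(lev) < 2) stop_mf("elastic net requires >= 2 groups")
  pairs <- utils::combn(lev, 2)

  out <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sel <- grp %in% c(a, b)
    if (sum(grp == a) < 3 || sum(grp == b) < 3)
      stop_mf("pair %s/%s needs >= 3 samples per group", a, b)
    X <- t(wide$values[, sel, drop = FALSE])
    y <- as.numeric(grp[sel] == b)
    cvfit <- withr::with_seed(seed,
      glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                        nlambda = n_lambda, lambda.min.ratio = 1e-4,
                        nfolds = cv_folds, standardize = TRUE))
    co <- stats::coef(cvfit, s = "lambda.min")
    co <- stats::setNames(as.numeric(co), rownames(co))[-1]   # drop intercept
    nz <- co[co != 0]
    out[[paste(a, "vs", b)]] <- list(selected = names(nz), coefficients = nz,
                                     lambda = cvfit$lambda.min, alpha = alpha,
                                     fit = cvfit)
    mf_log("elastic net ", a, " vs ", b, ": ", length(nz), " of ",
           ncol(X), " features selected (alpha = ", alpha, ")")
  }
  structure(out, class = "selection_result")
}

#' Coefficient-path plot for one group pair
#' @param selection a `selection_result`.
#' @param pair name of the comparison (default: first).
#' @return `NULL`; draws the glmnet coefficient path on the active device.
#' @export
enet_path_plot <- function(selection, pair = NULL) {
  pair <- pair %||% names(selection)[1]
  if (!pair %in% names(selection)) stop_mf("unknown comparison '%s'", pair)
  plot(selection[[pair]]$fit$glmnet.fit, xvar = "lambda")
  graphics::abline(v = log(selection[[pair]]$lambda), lty = 3)
  invisible(NULL)
}
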