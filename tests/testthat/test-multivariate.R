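# PCA, PLS-DA, LDA, hierarchical clustering, random forest, SVM, elastic net.

test_that("PCA conserves variance, orders components, reconstructs the data", {
  withr::with_seed(81, {
    d <- generate_synthetic(synthetic_spec(n_features = 15,
                                           n_samples_per_group = 10,
                                           n_signal = 5, effect_sizes = 4,
                                           seed = 81))
  })
  res <- pca(d$wide, d$design)
  expect_equal(sum(res$explained_all), 1, tolerance = 1e-12)
  expect_true(all(diff(res$explained_all) <= 1e-12))
  Xc <- scale(t(d$wide$values), center = TRUE, scale = FALSE)
  recon <- res$scores %*% t(res$loadings)
  expect_equal(recon, Xc, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("one-directional data loads a single principal component", {
  t_ <- seq(-1, 1, length.out = 8)
  v <- outer(c(1, 2, 3), t_)                   # rank-1 variation
  dimnames(v) <- list(c("F1", "F2", "F3"), sprintf("S%d", 1:8))
  res <- pca(feature_table(v))
  expect_equal(res$explained_all[1], 1, tolerance = 1e-12)
  expect_error(pca(make_wide(matrix(c(1, NA, 2, 3), 2))), "impute|missing")
})

test_that("PLS-DA separates separable groups and obeys label-swap symmetry", {
  withr::with_seed(82, {
    g1 <- matrix(rnorm(20 * 10), nrow = 20); g1[1:3, ] <- g1[1:3, ] + 6
    g2 <- matrix(rnorm(20 * 10), nrow = 20)
  })
  fx <- make_two_group(g1, g2)
  res <- plsda(fx$wide, fx$design, n_comp = 2)
  expect_equal(res$accuracy, 1)
  sc1 <- res$scores[, 1]
  grp <- fx$design$data$group
  expect_true(max(sc1[grp == "A"]) < min(sc1[grp == "B"]) ||
                min(sc1[grp == "A"]) > max(sc1[grp == "B"]))

  # swapped labels: scores flip sign, |weights| unchanged
  design2 <- fx$design
  design2$data$group <- ifelse(grp == "A", "B", "A")
  res2 <- plsda(fx$wide, design2, n_comp = 2)
  expect_equal(res2$scores[, 1], -res$scores[, 1], tolerance = 1e-9)
  expect_equal(abs(res2$weights), abs(res$weights), tolerance = 1e-9)

  # deflation order: one-component run equals the first component of two
  res1 <- plsda(fx$wide, fx$design, n_comp = 1)
  expect_equal(res1$scores[, 1], res$scores[, 1], tolerance = 1e-12)
})

test_that("PLS-DA enforces the two-group contract and the CV sample gate", {
  d <- generate_synthetic(synthetic_spec(n_features = 10,
                                         n_samples_per_group = 4,
                                         groups = c("A", "B", "C"), seed = 2))
  expect_error(plsda(d$wide, d$design), "two groups")
  d2 <- generate_synthetic(synthetic_spec(n_features = 10,
                                          n_samples_per_group = 4, seed = 2))
  expect_error(plsda(d2$wide, d2$design, cv = "single"), "larger than 100")
})

test_that("PLS-DA CV selects a component count on large samples", {
  d <- generate_synthetic(synthetic_spec(n_features = 20,
                                         n_samples_per_group = 60,
                                         n_signal = 5, effect_sizes = 3,
                                         seed = 83))
  res <- plsda(d$wide, d$design, n_comp = 3, cv = "single", seed = 1)
  expect_true(res$n_comp %in% 1:3)
  expect_gt(res$accuracy, 0.9)
})

test_that("LDA separates Gaussian clouds and caps the subspace dimension", {
  withr::with_seed(84, {
    g1 <- matrix(rnorm(5 * 12), nrow = 5) + c(8, 0, 0, 0, 0)
    g2 <- matrix(rnorm(5 * 12), nrow = 5)
  })
  fx <- make_two_group(g1, g2)
  res <- lda_project(fx$wide, fx$design)
  expect_equal(res$accuracy, 1)
  expect_equal(res$n_comp, 1)               # 2 groups -> exactly 1 axis
  expect_error(lda_project(fx$wide, fx$design, n_comp = 2), "smaller than")
})

test_that("centroid clustering joins duplicated samples first", {
  withr::with_seed(85, base <- matrix(rnorm(30), nrow = 10))
  v <- cbind(base, base[, 1])               # S4 duplicates S1
  dimnames(v) <- list(sprintf("F%02d", 1:10), c("S1", "S2", "S3", "S4"))
  cl <- hierarchical_heatmap(feature_table(v))
  expect_equal(length(cl$hclust_samples$order), 4)   # leaf count = samples
  first <- sort(abs(cl$hclust_samples$merge[1, ]))
  expect_equal(first, c(1, 4))              # duplicates merge at height 0
  expect_equal(cl$hclust_samples$height[1], 0)
  expect_error(hierarchical_heatmap(make_wide(matrix(c(1, NA, 2, 3), 2))),
               "missing|impute")
})

test_that("random forest ranks a perfectly class-determining feature first", {
  withr::with_seed(86, {
    noise1 <- matrix(rnorm(30 * 15), nrow = 30)
    noise2 <- matrix(rnorm(30 * 15), nrow = 30)
  })
  noise1[1, ] <- 0; noise2[1, ] <- 10       # F001 fully determines the class
  fx <- make_two_group(noise1, noise2)
  ranks <- vapply(1:10, function(s) {
    res <- rf_importance(fx$wide, fx$design, n_trees = 300, seed = s)
    which(res$importance$featureID == "F001")
  }, numeric(1))
  expect_equal(mean(ranks), 1)

  a <- rf_importance(fx$wide, fx$design, n_trees = 200, seed = 3)
  b <- rf_importance(fx$wide, fx$design, n_trees = 200, seed = 3)
  expect_identical(a$importance, b$importance)
  expect_true(all(is.finite(a$importance$importance)))
  expect_true(all(a$importance$importance >= 0))
})

test_that("SVM reaches perfect resubstitution on separable data; rbf solves XOR", {
  withr::with_seed(87, {
    g1 <- matrix(rnorm(10 * 12), nrow = 10) + 5
    g2 <- matrix(rnorm(10 * 12), nrow = 10)
  })
  fx <- make_two_group(g1, g2)
  res <- svm_classify(fx$wide, fx$design, wide_target = fx$wide,
                      kernel = "linear")
  expect_equal(res$training_accuracy, 1)
  expect_equal(unname(res$predictions), fx$design$data$group)

  # XOR pattern in 2 features: linear fails, rbf succeeds
  withr::with_seed(88, {
    n <- 40
    x1 <- c(rnorm(n, -2), rnorm(n, 2), rnorm(n, -2), rnorm(n, 2))
    x2 <- c(rnorm(n, -2), rnorm(n, 2), rnorm(n, 2), rnorm(n, -2))
  })
  cls <- rep(c("A", "A", "B", "B"), each = n)
  v <- rbind(f1 = x1, f2 = x2)
  colnames(v) <- sprintf("S%03d", seq_along(cls))
  wide <- feature_table(v)
  design <- make_design(colnames(v), group = cls)
  lin <- svm_classify(wide, design, kernel = "linear")
  rbf <- svm_classify(wide, design, kernel = "rbf")
  # a line can classify at most 3 of the 4 XOR clusters correctly
  expect_lt(lin$training_accuracy, 0.8)
  expect_gt(rbf$training_accuracy, 0.95)

  missing_target <- make_wide(matrix(rnorm(10), 5),
                              feature_ids = sprintf("X%d", 1:5))
  expect_error(svm_classify(fx$wide, fx$design, wide_target = missing_target),
               "missing training feature")
})

test_that("ridge keeps every feature while elastic net and LASSO select", {
  withr::with_seed(89, {
    d <- generate_synthetic(synthetic_spec(n_features = 52,
                                           n_samples_per_group = 20,
                                           n_signal = 2, effect_sizes = 3,
                                           seed = 89))
  })
  ridge <- elastic_net_select(d$wide, d$design, alpha = 0, seed = 1)
  expect_equal(length(ridge[[1]]$selected), 52)   # shrinkage only, no selection

  enet <- elastic_net_select(d$wide, d$design, alpha = 0.5, seed = 1)
  expect_true(all(c("F0001", "F0002") %in% enet[[1]]$selected))

  lasso <- elastic_net_select(d$wide, d$design, alpha = 1, seed = 1)
  expect_lte(length(lasso[[1]]$selected), length(enet[[1]]$selected))

  expect_error(elastic_net_select(d$wide, d$design, alpha = 1.5), "alpha")
})

test_that("projection scores are invariant to sample order", {
  d <- generate_synthetic(synthetic_spec(n_features = 12,
                                         n_samples_per_group = 6,
                                         n_signal = 3, effect_sizes = 4,
                                         seed = 90))
  res1 <- pca(d$wide, d$design)
  perm <- withr::with_seed(1, sample(ncol(d$wide$values)))
  wide2 <- feature_table(d$wide$values[, perm])
  res2 <- pca(wide2, d$design)
  nm <- rownames(res1$scores)
  # PCs are defined up to sign
  for (k in 1:3) {
    a <- res1$scores[nm, k]; b <- res2$scores[nm, k]
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-8)) ||
                  isTRUE(all.equal(a, -b, tolerance = 1e-8)))
  }
})
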