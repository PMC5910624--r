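# Feature-by-feature tests: t-tests, permutation, ANOVA, Kruskal-Wallis,
# multiple-testing adjustment.

test_that("one-sample t matches its closed form and symmetric conventions", {
  wide <- make_wide(rbind(sym = c(-1, 0, 1), pos = c(1, 2, 3)))
  res <- single_group_ttest(wide, mu0 = 0)
  expect_equal(res$statistic[1], 0)
  expect_equal(res$p_value[1], 1)
  # {1,2,3}: t = 2 / (1/sqrt(3)) = 3.464, df 2, p ~ 0.0742
  expect_equal(res$statistic[2], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$p_value[2], 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(round(res$p_value[2], 4), 0.0742)
  # cross-check with stats::t.test
  tt <- t.test(c(1, 2, 3), mu = 0)
  expect_equal(res$p_value[2], tt$p.value, tolerance = 1e-12)
})

test_that("two-group pooled t matches the worked example and t.test oracle", {
  fx <- make_two_group(matrix(c(1, 2, 3), 1), matrix(c(2, 3, 4), 1))
  res <- two_group_ttest(fx$wide, fx$design)
  expect_equal(res$statistic, -sqrt(3 / 2), tolerance = 1e-12)  # -1.2247
  expect_equal(res$df, 4)
  tt <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(res$estimate, -1)

  same <- make_two_group(matrix(c(5, 6, 7), 1), matrix(c(5, 6, 7), 1))
  r2 <- two_group_ttest(same$wide, same$design)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
})

test_that("paired tests reduce to one-sample tests on differences", {
  v <- rbind(F1 = c(10, 11, 12, 10 + 2, 11 + 2, 12 + 2))
  colnames(v) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  wide <- feature_table(v)
  design <- make_design(colnames(v), group = rep(c("A", "B"), each = 3),
                        pair = rep(c("p1", "p2", "p3"), 2))
  res <- two_group_ttest(wide, design, paired = TRUE, pair_col = "pair")
  expect_equal(res$estimate, -2)
  expect_equal(res$p_value, 0)               # constant shift, zero within-pair noise

  vi <- rbind(F1 = c(3, 4, 5, 3, 4, 5))
  colnames(vi) <- colnames(v)
  ident <- feature_table(vi)
  r0 <- two_group_ttest(ident, design, paired = TRUE, pair_col = "pair")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("zero-variance and tiny groups are handled per the stated conventions", {
  fx <- make_two_group(matrix(c(5, 5, 5), 1), matrix(c(7, 7, 7), 1))
  res <- two_group_ttest(fx$wide, fx$design)
  expect_equal(res$p_value, 0)
  expect_true(is.infinite(res$statistic))
  tiny <- make_two_group(matrix(1, 1, 1), matrix(c(1, 2), 1))
  expect_error(two_group_ttest(tiny$wide, tiny$design), "at least 2")
})

test_that("exhaustive permutation test equals the brute-force oracle exactly", {
  withr::with_seed(71, {
    g1 <- matrix(rnorm(15, 10), nrow = 5)
    g2 <- matrix(rnorm(15, 12), nrow = 5)
  })
  fx <- make_two_group(g1, g2)
  res <- permutation_test(fx$wide, fx$design, exact = TRUE)

  # oracle: enumerate all 20 label splits with t.test
  v <- fx$wide$values
  idx <- combn(6, 3)
  for (i in 1:5) {
    tobs <- abs(t.test(v[i, 1:3], v[i, 4:6], var.equal = TRUE)$statistic)
    tperm <- apply(idx, 2, function(j)
      abs(t.test(v[i, j], v[i, -j], var.equal = TRUE)$statistic))
    expect_equal(res$p_value[i], mean(tperm >= tobs - 1e-12))
  }
})

test_that("random permutation p-values respect the add-one bound and null behavior", {
  fx <- make_two_group(matrix(c(1, 2, 3, 4), 1), matrix(c(1, 2, 3, 4), 1))
  res <- permutation_test(fx$wide, fx$design, n_perm = 200, seed = 5)
  expect_gte(res$p_value, 1 / 201)
  expect_gt(res$p_value, 0.9)              # identical groups

  sig <- make_two_group(matrix(c(1, 2, 1, 2), 1), matrix(c(9, 10, 9, 10), 1))
  r2 <- permutation_test(sig$wide, sig$design, n_perm = 400, seed = 5)
  expect_lt(r2$p_value, 0.05)
  expect_gte(r2$p_value, 1 / 401)
})

test_that("single-factor ANOVA with two groups reproduces the pooled t-test", {
  withr::with_seed(72, {
    fx <- make_two_group(matrix(rnorm(40, 10), nrow = 8),
                         matrix(rnorm(40, 11), nrow = 8))
  })
  tt <- two_group_ttest(fx$wide, fx$design)
  av <- anova_fixed(fx$wide, fx$design, factors = "group")
  expect_equal(av$factors$F, tt$statistic^2, tolerance = 1e-10)
  expect_equal(av$factors$p_value, tt$p_value, tolerance = 1e-10)
  expect_equal(av$contrasts$p_value, tt$p_value, tolerance = 1e-10)
  expect_equal(av$contrasts$estimate, tt$estimate, tolerance = 1e-10)
})

test_that("three identical groups yield F near 0 and p near 1", {
  v <- matrix(rep(c(4, 5, 6), 3), nrow = 1)
  wide <- make_wide(v)
  design <- make_design(sample_ids(wide), group = rep(c("A", "B", "C"), each = 3))
  av <- anova_fixed(wide, design, factors = "group")
  expect_equal(av$factors$F, 0, tolerance = 1e-12)
  expect_equal(av$factors$p_value, 1, tolerance = 1e-12)
  expect_equal(nrow(av$contrasts), 3)      # all pairwise contrasts
})

test_that("balanced 2x2 ANOVA with interaction matches the cell-means oracle", {
  withr::with_seed(73, {
    cell <- expand.grid(f1 = c("a", "b"), f2 = c("x", "y"),
                        rep = 1:4, stringsAsFactors = FALSE)
    mu <- with(cell, 2 + (f1 == "b") * 1 + (f2 == "y") * 0.5 +
                 (f1 == "b" & f2 == "y") * 1.5)
    y <- mu + rnorm(nrow(cell))
  })
  v <- matrix(y, nrow = 1, dimnames = list("F1", sprintf("S%02d", seq_along(y))))
  wide <- feature_table(v)
  design <- design_table(data.frame(sampleID = colnames(v), f1 = cell$f1,
                                    f2 = cell$f2), id_col = "sampleID")
  av <- anova_fixed(wide, design, factors = c("f1", "f2"), interaction = TRUE)
  oracle <- anova(lm(y ~ f1 * f2, data = cell))
  expect_equal(av$factors$p_value[av$factors$term == "f1:f2"],
               oracle["f1:f2", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(av$diagnostics$mse, oracle["Residuals", "Mean Sq"],
               tolerance = 1e-10)
})

test_that("ANOVA supports covariates and rejects rank-deficient designs", {
  withr::with_seed(74, {
    grp <- rep(c("A", "B"), each = 6)
    cov1 <- rnorm(12)
    y <- 1 + (grp == "B") * 2 + 0.5 * cov1 + rnorm(12, sd = 0.3)
  })
  v <- matrix(y, nrow = 1, dimnames = list("F1", sprintf("S%02d", 1:12)))
  wide <- feature_table(v)
  design <- design_table(data.frame(sampleID = colnames(v), group = grp,
                                    weight = cov1), id_col = "sampleID")
  av <- anova_fixed(wide, design, factors = "group", covariates = "weight")
  oracle <- lm(y ~ grp + cov1)
  expect_equal(av$contrasts$estimate, -unname(coef(oracle)["grpB"]),
               tolerance = 1e-10)

  dup <- design_table(data.frame(sampleID = colnames(v), group = grp,
                                 group2 = grp), id_col = "sampleID")
  expect_error(anova_fixed(wide, dup, factors = c("group", "group2")),
               "aliased|rank")
})

test_that("Kruskal-Wallis reproduces the rank worked example and the R oracle", {
  fx <- make_two_group(matrix(c(1, 2, 3), 1), matrix(c(4, 5, 6), 1))
  kw <- kruskal_wallis(fx$wide, fx$design)
  # ranks 1..6, R1 = 6, R2 = 15 -> H = 12/(6*7) * (12 + 75) - 21 = 27/7
  expect_equal(kw$results$H, 27 / 7, tolerance = 1e-12)
  expect_equal(round(kw$results$H, 3), 3.857)
  expect_equal(kw$results$df, 1)
  kt <- kruskal.test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$results$p_value, kt$p.value, tolerance = 1e-12)
  expect_equal(kw$contrasts$estimate, 2 - 5)

  tied <- make_two_group(matrix(c(7, 7, 7), 1), matrix(c(7, 7, 7), 1))
  kwt <- kruskal_wallis(tied$wide, tied$design)
  expect_equal(kwt$results$H, 0)
  expect_equal(kwt$results$p_value, 1)
})

test_that("Kruskal-Wallis p-values are roughly uniform under the null", {
  d <- generate_synthetic(synthetic_spec(n_features = 400,
                                         n_samples_per_group = 8,
                                         groups = c("A", "B", "C"), seed = 19))
  kw <- kruskal_wallis(d$wide, d$design)
  expect_lt(abs(mean(kw$results$p_value < 0.05) - 0.05),
            qnorm(0.995) * sqrt(0.05 * 0.95 / 400) + 0.01)
})

test_that("multiple-testing adjustments match the worked examples", {
  p <- c(0.01, 0.02, 0.03)
  res <- adjust_pvalues(p)
  expect_equal(res$p_bonferroni, c(0.03, 0.06, 0.09))
  expect_equal(res$p_bh, c(0.03, 0.03, 0.03))
  expect_equal(res$p_by, pmin(1, c(0.03, 0.03, 0.03) * (1 + 1/2 + 1/3)))
  # m = 1: everything unchanged
  one <- adjust_pvalues(0.2)
  expect_equal(unlist(one[c("p_bonferroni", "p_bh", "p_by")]),
               c(p_bonferroni = 0.2, p_bh = 0.2, p_by = 0.2))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "outside")
})

test_that("adjustment invariants: adjusted >= raw, BY >= BH, BH monotone", {
  withr::with_seed(75, p <- runif(200)^2)
  res <- adjust_pvalues(p)
  expect_true(all(res$p_bonferroni >= p))
  expect_true(all(res$p_bh >= p - 1e-15))
  expect_true(all(res$p_by >= res$p_bh - 1e-15))
  ord <- order(p)
  expect_true(all(diff(res$p_bh[ord]) >= -1e-15))
})

test_that("significance flags are nested across levels", {
  withr::with_seed(76, {
    fx <- make_two_group(matrix(rnorm(300), nrow = 50),
                         matrix(rnorm(300, 0.8), nrow = 50))
  })
  res <- two_group_ttest(fx$wide, fx$design)
  expect_true(all(res$flag_001 <= res$flag_01))
  expect_true(all(res$flag_01 <= res$flag_05))
})
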