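# Blank feature filtering, threshold flags, scaling, g-log, imputation.

test_that("BFF computes the LOD from blanks and compares group means", {
  # F1: blanks {10,10,10} -> LOD 10; group mean 100 clears it
  # F2: blanks {10,20,30} -> mean 20, sd 10, LOD 50; group mean 40 flagged
  v <- rbind(F1 = c(10, 10, 10, 100, 100, 100),
             F2 = c(10, 20, 30, 35, 40, 45))
  colnames(v) <- c("B1", "B2", "B3", "S1", "S2", "S3")
  wide <- feature_table(v)
  design <- make_design(colnames(v), group = rep(c("blank", "trt"), each = 3))
  fl <- blank_feature_filter(wide, design, blank_group = "blank", k_sd = 3)
  expect_equal(attr(fl, "lod"), c(F1 = 10, F2 = 50))
  expect_equal(fl$flag_bff_trt, c(0L, 1L))
  expect_equal(fl$flag_bff_all, c(0L, 1L))
})

test_that("BFF handles all-missing blanks (LOD 0, never flagged) and absent blank group", {
  v <- rbind(F1 = c(NA, NA, 5, 5))
  colnames(v) <- c("B1", "B2", "S1", "S2")
  wide <- feature_table(v)
  design <- make_design(colnames(v), group = c("blank", "blank", "trt", "trt"))
  fl <- blank_feature_filter(wide, design, blank_group = "blank")
  expect_equal(attr(fl, "lod"), c(F1 = 0))
  expect_equal(fl$flag_bff_trt, 0L)
  expect_error(blank_feature_filter(wide, design, blank_group = "nope"),
               "blank group")
})

test_that("threshold flags use a strictly-greater-than-50% rule with missing as below", {
  # sweep the below-cutoff count in a 10-sample group: flag iff count > 5
  for (k in 0:10) {
    vals <- c(rep(0, k), rep(10, 10 - k))
    wide <- make_wide(matrix(vals, nrow = 1))
    design <- make_design(sample_ids(wide), group = rep("G", 10))
    fl <- threshold_flags(wide, design, cutoff = 5)
    expect_equal(fl$flag_threshold_G, as.integer(k > 5), info = paste("k =", k))
  }
  # 4-sample group, exactly 2 below: 50% is not more than 50%
  wide <- make_wide(matrix(c(0, 0, 10, 10), nrow = 1))
  design <- make_design(sample_ids(wide), group = rep("G", 4))
  expect_equal(threshold_flags(wide, design, cutoff = 5)$flag_threshold_G, 0L)
  # missing counts as below
  wide <- make_wide(matrix(c(NA, NA, 0, 10), nrow = 1))
  expect_equal(threshold_flags(wide, design, cutoff = 5)$flag_threshold_G, 1L)
})

test_that("per-feature scalings match their closed forms", {
  wide <- make_wide(matrix(c(1, 2, 3), nrow = 1))
  expect_equal(unname(scale_features(wide, "pareto")$values[1, ]),
               c(-1, 0, 1))                       # m = 2, s = 1
  expect_equal(unname(scale_features(wide, "center")$values[1, ]),
               c(-1, 0, 1))
  expect_equal(unname(scale_features(wide, "range")$values[1, ]),
               c(-0.5, 0, 0.5))
  expect_equal(unname(scale_features(wide, "level")$values[1, ]),
               c(-0.5, 0, 0.5))
  # sum normalization of sample {1,2,3} -> thirds of total
  col <- make_wide(matrix(c(1, 2, 3), ncol = 1))
  out <- scale_features(col, "none", sample_factor = "sum")
  expect_equal(unname(out$values[, 1]), c(1, 2, 3) / 6)
})

test_that("scaling invariants hold on random data and vast = autoscale * m/s", {
  withr::with_seed(42, {
    wide <- make_wide(matrix(rexp(200, 0.1), nrow = 20))
    ctr <- scale_features(wide, "center")
    expect_equal(unname(rowMeans(ctr$values)), rep(0, 20), tolerance = 1e-9)
    auto <- scale_features(wide, "autoscale")
    expect_equal(unname(apply(auto$values, 1, sd)), rep(1, 20), tolerance = 1e-9)
    m <- rowMeans(wide$values); s <- apply(wide$values, 1, sd)
    vast <- scale_features(wide, "vast")
    expect_equal(vast$values, auto$values * (m / s), tolerance = 1e-12)
  })
})

test_that("degenerate features are set missing, not an error", {
  wide <- make_wide(rbind(c(5, 5, 5), c(1, 2, 3)))
  out <- scale_features(wide, "autoscale")
  expect_true(all(is.na(out$values[1, ])))
  expect_false(anyNA(out$values[2, ]))
  expect_equal(attr(out, "degenerate"), "F001")
})

test_that("g-log matches its closed form and reduces to plain log at lambda 0", {
  wide <- make_wide(matrix(8, 1, 1))
  expect_equal(unname(log_transform(wide, base = 2)$values[1, 1]), 3)
  zero <- make_wide(matrix(0, 1, 1))
  expect_equal(unname(log_transform(zero, base = "e", glog_lambda = 4)$values[1, 1]),
               0)                                  # ln((0 + 2)/2)
  withr::with_seed(1, {
    pos <- make_wide(matrix(rexp(60) + 0.1, nrow = 6))
    expect_equal(log_transform(pos, base = 10, glog_lambda = 0)$values,
                 log10(pos$values), tolerance = 1e-12)
  })
  neg <- make_wide(matrix(c(-1, 2), 1))
  expect_error(log_transform(neg, base = 2), "positive")
})

test_that("g-log is monotone increasing in x for any lambda >= 0", {
  x <- sort(runif(50, -5, 50))
  for (lam in c(0.5, 1, 10, 1000)) {
    g <- log((x + sqrt(x^2 + lam)) / 2)
    wide <- make_wide(matrix(x, nrow = 1))
    got <- log_transform(wide, base = "e", glog_lambda = lam)$values[1, ]
    expect_equal(unname(got), g)
    expect_true(all(diff(got) > 0))
  }
})

test_that("group mean/median imputation fills with the group statistic only", {
  v <- rbind(F1 = c(1, 2, NA, 3, 100, 100, NA))
  colnames(v) <- sprintf("S%d", 1:7)
  wide <- feature_table(v)
  design <- make_design(colnames(v), group = c(rep("A", 4), rep("B", 3)))
  out <- impute(wide, design, "group_mean")
  expect_equal(unname(out$values[1, "S3"]), 2)     # mean of {1,2,3}
  expect_equal(unname(out$values[1, "S7"]), 100)
  expect_equal(out$values[1, c("S1", "S2", "S4")], v[1, c("S1", "S2", "S4")])
  med <- impute(wide, design, "group_median")
  expect_equal(unname(med$values[1, "S3"]), 2)
})

test_that("knn imputation copies the nearest co-observed profile at k = 1", {
  # S2 is identical to S1 on co-observed features; S3 is far away
  v <- rbind(F1 = c(5, 5, 50),
             F2 = c(7, 7, 70),
             F3 = c(NA, 9, 90))
  colnames(v) <- c("S1", "S2", "S3")
  wide <- feature_table(v)
  design <- make_design(colnames(v), group = rep("G", 3))
  out <- impute(wide, design, "knn", k = 1)
  expect_equal(unname(out$values["F3", "S1"]), 9)
})

test_that("stochastic imputation is seed-reproducible and never alters observed cells", {
  withr::with_seed(3, {
    v <- matrix(rpois(200, 50) + 0.0, nrow = 20)
    v[sample(length(v), 30)] <- NA
    dimnames(v) <- list(sprintf("F%02d", 1:20), sprintf("S%02d", 1:10))
  })
  wide <- feature_table(v)
  design <- make_design(colnames(v), group = rep(c("A", "B"), each = 5))
  a <- impute(wide, design, "stochastic_normal", seed = 10)
  b <- impute(wide, design, "stochastic_normal", seed = 10)
  c2 <- impute(wide, design, "stochastic_normal", seed = 11)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c2$values))
  obs <- !is.na(v)
  expect_identical(a$values[obs], v[obs])
  expect_true(all(a$values[!obs] >= 0))            # truncated at zero
  pois <- impute(wide, design, "stochastic_poisson", seed = 10)
  expect_identical(pois$values[obs], v[obs])
  expect_true(all(pois$values[!obs] == round(pois$values[!obs])))
})

test_that("stochastic normal draws recover the fitted group mean", {
  withr::with_seed(8, {
    v <- matrix(rnorm(2000, mean = 100, sd = 5), nrow = 2)
  })
  dimnames(v) <- list(c("F1", "F2"), sprintf("S%04d", 1:1000))
  v[1, 1:400] <- NA
  mu_hat <- mean(v[1, 401:1000])
  sd_hat <- sd(v[1, 401:1000])
  wide <- feature_table(v)
  design <- make_design(colnames(v), group = rep("G", 1000))
  out <- impute(wide, design, "stochastic_normal", seed = 4)
  draws <- out$values[1, 1:400]
  expect_lt(abs(mean(draws) - mu_hat), 3 * sd_hat / sqrt(400))
})

test_that("knn with k >= group size is reduced with a warning in the log", {
  v <- rbind(F1 = c(1, 2, NA), F2 = c(1, 1, 1))
  colnames(v) <- c("S1", "S2", "S3")
  wide <- feature_table(v)
  design <- make_design(colnames(v), group = rep("G", 3))
  withr::with_options(list(metaboflag.log_level = "WARN"), {
    expect_message(out <- impute(wide, design, "knn", k = 10), "reduced")
  })
  expect_false(anyNA(out$values))
})
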