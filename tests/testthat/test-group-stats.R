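# Inferential machinery: pooled t, label-permutation tests, BH-FDR against a
# brute-force oracle, and the Pearson correlation test.

test_that("pooled two-sample t matches the hand computation", {
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3 / sqrt(1 * (1 / 3 + 1 / 3)))  # pooled sd 1
  expect_equal(round(tt$t, 3), -3.674)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 2 * pt(tt$t, 4))

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  scaled <- two_sample_t(10 * c(1, 2, 3), 10 * c(4, 5, 6))
  expect_equal(scaled$t, tt$t)

  expect_error(two_sample_t(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("permutation p-values behave at the degenerate extremes", {
  labels <- rep(c("control", "case"), c(12L, 8L))
  x <- cbind(constant = rep(3, 20),
             separated = c(rep(0, 12), rep(100, 8)) + (1:20) * 1e-6)
  pt <- permutation_test_nodewise(x, labels, n_perm = 500, seed = 2)
  expect_equal(unname(pt$p[1]), 1)              # no signal at all
  expect_equal(unname(pt$p[2]), 1 / 501)        # minimum attainable
  expect_error(permutation_test_nodewise(x, labels, n_perm = 0), "n_perm")
  expect_error(permutation_test_nodewise(x[1:3, ], rep("control", 3)), "group")
})

test_that("permutation p depends on the data only through t, and is seed-reproducible", {
  set.seed(51)
  labels <- rep(c("control", "case"), c(6L, 5L))
  x <- matrix(rnorm(11 * 4), 11, 4)
  p1 <- permutation_test_nodewise(x, labels, n_perm = 300, seed = 9)
  p2 <- permutation_test_nodewise(x, labels, n_perm = 300, seed = 9)
  expect_identical(p1, p2)
  # An affine transform of one node's values preserves its t and hence its p.
  x2 <- x
  x2[, 2] <- 5 * x[, 2] - 7
  p3 <- permutation_test_nodewise(x2, labels, n_perm = 300, seed = 9)
  expect_equal(p3$t[2], p1$t[2])
  expect_equal(p3$p, p1$p)
})

test_that("null permutation p-values are approximately uniform", {
  labels <- rep(c("control", "case"), c(6L, 6L))
  ps <- unlist(lapply(1:200, function(r) {
    x <- withr::with_seed(1000 + r, matrix(rnorm(12 * 10), 12, 10))
    permutation_test_nodewise(x, labels, n_perm = 200, seed = 2000 + r)$p
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment matches the hand example and the brute-force oracle", {
  adj <- fdr_bh(c(0.001, 0.012, 0.014, 0.8))
  expect_equal(adj$q, c(0.004, 0.014 * 4 / 3, 0.014 * 4 / 3, 0.8))
  expect_equal(adj$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(fdr_bh(rep(1, 10))$significant))
  expect_true(fdr_bh(0.04)$significant)

  set.seed(52)
  for (r in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_bh(p)$q, bf_bh(p))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pearson correlation test matches closed forms", {
  ct <- pearson_correlation_test(1:5, c(2, 1, 4, 3, 5))
  expect_equal(ct$r, 0.8)
  expect_equal(ct$df, 3)
  expect_equal(ct$t, 0.8 * sqrt(3) / sqrt(1 - 0.64))
  expect_equal(ct$p, 2 * pt(-abs(ct$t), 3))

  perfect <- pearson_correlation_test(1:4, 2 * (1:4) + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p, 0)
  expect_true(perfect$degenerate)

  x <- c(-1, 1, -1, 1); y <- c(-1, -1, 1, 1)
  expect_equal(pearson_correlation_test(x, y)$r, 0)
  expect_error(pearson_correlation_test(1:3, rep(2, 3)), "variance")
})

test_that("global comparison reports the full measure battery with C-Q correlations", {
  set.seed(53)
  df <- data.frame(subject_id = sprintf("s%02d", 1:12),
                   group = rep(c("control", "case"), each = 6L),
                   grand_mean_raw = rnorm(12, 0.01, 0.002),
                   grand_mean_nonnegative = rnorm(12, 0.2, 0.01),
                   grand_mean_thresholded = rnorm(12, 0.45, 0.02),
                   L = rnorm(12, 2.2, 0.1), C = rnorm(12, 0.58, 0.05),
                   gamma = rnorm(12, 2.8, 0.2), lambda = rnorm(12, 1.2, 0.08),
                   sigma = rnorm(12, 2.3, 0.1), Q = rnorm(12, 0.38, 0.03))
  out <- compare_global_metrics(df)
  expect_equal(sum(out$scope == "global_metric"), 9L)
  expect_setequal(out$identifier[out$scope == "correlation"],
                  c("C_vs_Q_control", "C_vs_Q_case"))
  row_l <- out[out$identifier == "L", ]
  tt <- two_sample_t(df$L[df$group == "control"], df$L[df$group == "case"])
  expect_equal(row_l$t, tt$t)
  expect_equal(row_l$mean_control, mean(df$L[df$group == "control"]))
  ct <- pearson_correlation_test(df$C[df$group == "control"],
                                 df$Q[df$group == "control"])
  expect_equal(out$r[out$identifier == "C_vs_Q_control"], ct$r)
})

test_that("identically drawn groups rarely flag any global measure", {
  # 100 null replicates of the grand-mean battery (type-I behaviour at
  # alpha = 0.05 per measure, so ~5 rejections per measure expected).
  set.seed(54)
  measures <- c("grand_mean_raw", "grand_mean_nonnegative", "grand_mean_thresholded")
  hits <- matrix(0L, 100L, length(measures), dimnames = list(NULL, measures))
  for (r in 1:100) {
    df <- data.frame(subject_id = sprintf("s%02d", 1:30),
                     group = rep(c("control", "case"), c(16L, 14L)),
                     grand_mean_raw = rnorm(30, 0.005, 0.005),
                     grand_mean_nonnegative = rnorm(30, 0.2, 0.02),
                     grand_mean_thresholded = rnorm(30, 0.45, 0.05))
    out <- compare_global_metrics(df, measures = measures)
    hits[r, ] <- as.integer(out$significant)
  }
  expect_true(all(colMeans(hits) <= 0.10))
})

test_that("node-wise comparison flags directions symmetrically under relabeling", {
  set.seed(55)
  labels <- rep(c("control", "case"), c(6L, 5L))
  mats <- list(metric_a = matrix(rnorm(11 * 8), 11, 8))
  mats$metric_a[labels == "case", 3] <- mats$metric_a[labels == "case", 3] + 5
  out <- compare_node_metrics(mats, labels, n_perm = 400, seed = 6)
  expect_equal(nrow(out), 8L)
  expect_equal(out$direction[out$node_id == 2], "case_higher")

  flipped <- ifelse(labels == "control", "case", "control")
  out2 <- compare_node_metrics(mats, flipped, n_perm = 400, seed = 6)
  swap <- c(case_higher = "control_higher", control_higher = "case_higher")
  expect_equal(out2$direction, unname(swap[out$direction]))
  expect_equal(out2$mean_control, out$mean_case)
})
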