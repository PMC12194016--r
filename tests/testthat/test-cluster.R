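test_that("Ward merge heights match the brute-force agglomeration oracle", {
  # hand-computed 1-D case: {0, 1} merge at height 1, then {0.5} vs {10}
  # at sqrt(2 * 2 * 1 / 3) * 9.5
  x <- matrix(c(0, 1, 10), ncol = 1)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  expect_equal(hc$height, c(1, sqrt(4 / 3) * 9.5), tolerance = 1e-12)
  expect_equal(ward_oracle(x), hc$height, tolerance = 1e-12)

  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- sample(4:6, 1)
      x <- matrix(rnorm(n * 2), ncol = 2)
      hc <- stats::hclust(stats::dist(x), method = "ward.D2")
      expect_equal(sort(ward_oracle(x)), sort(hc$height), tolerance = 1e-8)
    }
  })
})

test_that("silhouette widths equal the brute-force definition", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      x <- matrix(rnorm(50 * 2), ncol = 2)
      lab <- sample(1:3, 50, replace = TRUE)
      s_pkg <- cluster::silhouette(lab, stats::dist(x))[, "sil_width"]
      expect_equal(unname(s_pkg), silhouette_oracle(x, lab), tolerance = 1e-12)
    }
  })
})

test_that("the adjusted Rand index matches the reference implementation", {
  withr::with_seed(61, {
    for (rep in 1:10) {
      a <- sample(1:3, 40, replace = TRUE)
      b <- sample(1:4, 40, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
})

test_that("well-separated blobs are recovered exactly at k = 2", {
  withr::with_seed(9, {
    x <- rbind(matrix(rnorm(80, 0), ncol = 2),
               matrix(rnorm(80, 6), ncol = 2))
    truth <- rep(1:2, each = 40)
  })
  cl <- ward_cluster(x, B = 25, seed = 99)
  expect_equal(cl$k, 2L)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  expect_gt(cl$silhouette, 0.5)
  expect_equal(nrow(cl$bootstrap), 25L)
  expect_gt(mean(cl$bootstrap$agreement), 0.95)
})

test_that("degenerate inputs are refused", {
  expect_error(ward_cluster(matrix(1, nrow = 20, ncol = 2)), "degenerate")
  expect_error(ward_cluster(matrix(rnorm(10), ncol = 2), k_range = 1:10),
               "more candidate clusters")
  expect_error(ward_cluster(matrix(c(rnorm(20), rep(NA, 2)), ncol = 2)), "finite")
})

test_that("weak structure falls back to a single cluster when allowed", {
  # one isotropic Gaussian blob: no split clears a demanding silhouette bar
  withr::with_seed(41, x <- matrix(rnorm(400), ncol = 2))
  cl <- ward_cluster(x, k_range = 1:6, B = 0, weak_threshold = 0.45)
  expect_true(cl$weak_structure)
  expect_equal(cl$k, 1L)
  expect_true(all(cl$labels == 1L))
  expect_true(all(cl$silhouette_by_k$silhouette < 0.45))
  # without k = 1 in the range the best weak solution is reported
  cl2 <- ward_cluster(x, k_range = 2:6, B = 0, weak_threshold = 0.45)
  expect_gte(cl2$k, 2L)
  expect_false(cl2$weak_structure)
})

test_that("cluster contrasts combine Welch t with pooled-SD effect size", {
  x <- c(1, 2, 3, 4, 5)
  out <- compare_clusters(x, x)
  expect_equal(out$t, 0)
  expect_equal(out$d, 0)
  # exact one-pooled-SD shift
  withr::with_seed(2, y <- rnorm(50))
  sp <- stats::sd(y)
  out <- compare_clusters(y, y + sp)
  expect_equal(out$d, 1, tolerance = 1e-12)
  # oracle check of the Welch statistic
  a <- c(1, 3, 4, 7); b <- c(2, 9, 11, 12, 15)
  out <- compare_clusters(a, b)
  tt <- stats::t.test(b, a)
  expect_equal(out$t, unname(tt$statistic))
  expect_equal(out$df, unname(tt$parameter))
  expect_error(compare_clusters(c(1, 1), c(1, 1)), "zero variance")
})

test_that("correlation confidence intervals behave like Fisher-z intervals", {
  x <- 1:10
  ident <- correlation_ci(x, x)
  expect_equal(ident$r, 1)
  expect_equal(ident$ci_upper - ident$ci_lower, 0)
  expect_error(correlation_ci(rep(1, 10), x), "constant")
  withr::with_seed(3, y <- x + rnorm(10, 0, 0.01))
  out <- correlation_ci(x, y)
  expect_gt(out$r, 0.999)
  expect_lt(out$ci_upper - out$ci_lower, 0.01)
  out_neg <- correlation_ci(x, -y)
  expect_equal(out_neg$r, -out$r)
  # coverage of zero under independence
  cover <- withr::with_seed(77, vapply(1:500, function(i) {
    a <- rnorm(30); b <- rnorm(30)
    ci <- correlation_ci(a, b)
    ci$ci_lower <= 0 && ci$ci_upper >= 0
  }, logical(1)))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})
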