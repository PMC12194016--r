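# synthetic standardized path data with known coefficients
sim_paths <- function(n, a1 = 0, a2 = 0, b1 = 0, b2 = 0, cp = 0) {
  x <- rnorm(n)
  m1 <- a1 * x + rnorm(n, 0, sqrt(max(1 - a1^2, 0.05)))
  m2 <- a2 * x + rnorm(n, 0, sqrt(max(1 - a2^2, 0.05)))
  ey <- max(1 - (cp^2 + b1^2 + b2^2), 0.05)
  y <- cp * x + b1 * m1 + b2 * m2 + rnorm(n, 0, sqrt(ey))
  list(x = x, m1 = m1, m2 = m2, y = y)
}

test_that("path estimates match the closed-form normal equations", {
  d <- withr::with_seed(1, sim_paths(300, a1 = 0.5, a2 = -0.3, b1 = 0.4, cp = 0.2))
  fit <- mediation_path(d$x, d$m1, d$m2, d$y, B = 0)
  R <- stats::cor(cbind(d$x, d$m1, d$m2, d$y))
  oracle <- paths_oracle(R)
  est <- setNames(fit$paths$estimate, fit$paths$path)
  expect_equal(unname(est["a1"]), oracle$a1, tolerance = 1e-10)
  expect_equal(unname(est["b1"]), unname(oracle$b1), tolerance = 1e-10)
  expect_equal(unname(est["direct"]), unname(oracle$direct), tolerance = 1e-10)
  # identity: total = direct + both indirect effects
  expect_equal(unname(est["total"]),
               unname(est["direct"] + est["indirect1"] + est["indirect2"]),
               tolerance = 1e-12)
})

test_that("standardized paths are invariant to affine rescaling of inputs", {
  d <- withr::with_seed(6, sim_paths(200, a1 = 0.4, b1 = -0.3))
  f1 <- mediation_path(d$x, d$m1, d$m2, d$y, B = 0)
  f2 <- mediation_path(100 + 7 * d$x, -2 * d$m1, d$m2 / 3, 50 * d$y, B = 0)
  # sign flips follow the rescaling; magnitudes are unchanged
  expect_equal(abs(f1$paths$estimate), abs(f2$paths$estimate), tolerance = 1e-10)
})

test_that("the saturated variant has zero discrepancy and df", {
  d <- withr::with_seed(2, sim_paths(150, a1 = 0.5, a2 = 0.4, b1 = 0.2))
  fit <- mediation_path(d$x, d$m1, d$m2, d$y, B = 0, free_mediator_cov = TRUE)
  expect_equal(fit$fit$df, 0L)
  expect_equal(fit$fit$chisq, 0, tolerance = 1e-8)
  expect_equal(fit$fit$rmsea, 0)
  constrained <- mediation_path(d$x, d$m1, d$m2, d$y, B = 0)
  expect_equal(constrained$fit$df, 1L)
  expect_gt(constrained$fit$chisq, 0)
  expect_lte(constrained$fit$cfi, 1)
  expect_gte(constrained$fit$srmr, 0)
})

test_that("large samples recover a planted indirect effect", {
  d <- withr::with_seed(10, sim_paths(5000, a1 = 0.5, b1 = -0.4))
  fit <- mediation_path(d$x, d$m1, d$m2, d$y, B = 0)
  est <- setNames(fit$paths$estimate, fit$paths$path)
  expect_lt(abs(est[["indirect1"]] - (0.5 * -0.4)), 0.03)
  expect_lt(abs(est[["indirect2"]]), 0.03)
})

test_that("point estimates are bootstrap-seed invariant, intervals sensible", {
  d <- withr::with_seed(3, sim_paths(120, a1 = 0.5, b1 = -0.4, cp = -0.2))
  f1 <- mediation_path(d$x, d$m1, d$m2, d$y, B = 300, seed = 1)
  f2 <- mediation_path(d$x, d$m1, d$m2, d$y, B = 300, seed = 2)
  expect_equal(f1$paths$estimate, f2$paths$estimate, tolerance = 1e-12)
  expect_false(identical(f1$paths$ci_lower, f2$paths$ci_lower))
  # the interval contains its point estimate
  expect_true(all(f1$paths$ci_lower <= f1$paths$estimate + 1e-9 &
                    f1$paths$estimate <= f1$paths$ci_upper + 1e-9))
  ind1 <- f1$paths[f1$paths$path == "indirect1", ]
  expect_lt(ind1$ci_upper, 0)  # clearly negative planted effect
})

test_that("null indirect effects are covered by bootstrap intervals", {
  cover <- withr::with_seed(12, vapply(1:40, function(i) {
    d <- sim_paths(200, a1 = 0.5, a2 = 0.3, cp = 0.3)  # b1 = b2 = 0
    fit <- mediation_path(d$x, d$m1, d$m2, d$y, B = 200, seed = i)
    ind <- fit$paths[fit$paths$path %in% c("indirect1", "indirect2"), ]
    c(ind$ci_lower <= 0 & 0 <= ind$ci_upper)
  }, logical(2)))
  expect_gte(mean(cover), 0.9)
})

test_that("a pipeline null cohort yields indirect effects centred on zero", {
  # all couplings that would link interrule times to the mediators are off;
  # abandonment and right-censoring are disabled too, since both couple
  # times, jump counts and score through a common cause (motivation, or the
  # time limit truncating slow attempts)
  cfg <- generator_config(
    n_participants = 120, p_structured = 1,
    coupling = list(intra = 0, jumps_base = c(structured = -0.7, unstructured = 1.3),
                    jumps_gap = 0, jump_failure = 0),
    iap = c(shape1 = 1e-6, shape2 = 1), time_limit = Inf)
  ests <- vapply(1:10, function(s) {
    co <- generate_cohort(cfg, seed = 400 + s)
    f <- participant_features(co$sessions, co$item_bank,
                              inter_denominator = "rules1")
    fp <- f$participants
    fit <- mediation_path(fp$inter, fp$intra, fp$jump_score, fp$score, B = 0)
    est <- setNames(fit$paths$estimate, fit$paths$path)
    c(est[["indirect1"]], est[["indirect2"]])
  }, numeric(2))
  expect_lt(abs(median(ests[1, ])), 0.05)
  expect_lt(abs(median(ests[2, ])), 0.05)
})

test_that("degenerate mediation inputs are rejected", {
  expect_error(mediation_path(1:20, 1:20, rnorm(20), rnorm(20)), "at least 30")
  x <- rnorm(40)
  expect_error(mediation_path(x, x, rnorm(40), rnorm(40)), "singular|constant")
})
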