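bank <- tiny_bank()

jump_log <- function(syms, iid = "it1", n = length(syms)) {
  as_sessions(ev_block("p1", iid, seq_len(n), syms, "submit", n + 1), bank)
}

test_that("rule-jump scores count executed minus necessary transitions", {
  # blockwise processing of a 2-rule item: optimal, score 0
  expect_equal(rule_jump_score(jump_log(c("a1", "a2", "b1", "b2")), 2), 0L)
  # alternating clicks: three transitions, score 2
  expect_equal(rule_jump_score(jump_log(c("a1", "b1", "a2", "b2")), 2), 2L)
  # abandoned 3-rule item touched one rule only: negative score
  expect_equal(rule_jump_score(jump_log(c("a1", "a2"), iid = "it2"), 3), -2L)
  # invariant: reordering clicks within a rule block changes nothing
  expect_equal(rule_jump_score(jump_log(c("a2", "a1", "b2", "b1")), 2), 0L)
})

test_that("test scores count exactly correct multi-rule items", {
  ev <- dplyr::bind_rows(
    ev_block("p1", "it1", c(1, 2, 3), c("a1", "a2", "b1"), "submit", 4),
    ev_block("p1", "it2", c(1, 2, 3, 4), c("a1", "b1", "c1", "c2"), "submit", 5),
    ev_block("p2", "it1", c(1, 2, 3), c("a1", "a2", "b2"), "submit", 4),
    ev_block("p2", "it2", c(1, 2), c("a1", "b1"), "timeout", 90)
  )
  sc <- test_score(as_sessions(ev, bank), bank)
  expect_equal(sc$score[sc$participant_id == "p1"], 2L)
  expect_equal(sc$score[sc$participant_id == "p2"], 0L)
})

test_that("item statistics match the classical formulas", {
  # two parallel items: alpha is exactly 1
  m <- matrix(c(1, 0, 1, 0), nrow = 2, dimnames = list(NULL, c("i1", "i2")))
  st <- item_stats(m)
  expect_equal(st$items$p, c(0.5, 0.5))
  expect_equal(st$alpha, 1)

  # computed alpha equals the covariance-form oracle exactly
  withr::with_seed(21, {
    for (rep in 1:10) {
      x <- matrix(rbinom(100, 1, runif(1, 0.2, 0.8)), nrow = 5, ncol = 20)
      if (stats::var(rowSums(x)) == 0) next
      st <- suppressWarnings(item_stats(x))
      expect_equal(st$alpha, alpha_oracle(x), tolerance = 1e-12)
    }
  })

  # item-rest correlation against a direct computation
  withr::with_seed(8, {
    x <- matrix(rbinom(200, 1, 0.5), nrow = 20)
    st <- suppressWarnings(item_stats(x))
    j <- 3
    expect_equal(st$items$r_rest[j], stats::cor(x[, j], rowSums(x[, -j])))
  })

  expect_error(item_stats(matrix(1, 5, 1)), "at least 2 items")
  expect_warning(item_stats(cbind(i1 = c(1, 1, 1), i2 = c(0, 1, 0))),
                 "zero-variance")
})

test_that("independent items produce near-zero alpha", {
  alphas <- withr::with_seed(31, vapply(1:20, function(r) {
    x <- matrix(rbinom(400 * 20, 1, 0.5), nrow = 400)
    item_stats(x)$alpha
  }, numeric(1)))
  expect_lt(median(abs(alphas)), 0.15)
})

test_that("acceleration is the first-third minus last-third mean", {
  expect_equal(acceleration(rep(4, 22)), 0)
  expect_equal(acceleration(22:1), 15)  # first seven mean 19, last seven mean 4
  # decreasing times give a positive (accelerating) sign
  expect_gt(acceleration(seq(10, 1, length.out = 12)), 0)
  # missing values are ignored within thirds
  x <- c(10, NA, 10, 4, 4, 4, 2, NA, 2)
  expect_equal(acceleration(x), 10 - 2)
  expect_error(acceleration(c(1, 2)), "at least 3")
})

test_that("response-to-difficulty slopes behave like correlations", {
  d <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(rtd_slope(1 + 2 * d, d), 1)
  expect_equal(rtd_slope(5 - 3 * d, d), -1)
  # raw slope preserves seconds-per-difficulty units
  expect_equal(rtd_slope(1 + 2 * d, d, standardized = FALSE), 2)
  expect_error(rtd_slope(c(1, 2), c(0.1, 0.2)), "at least 3")
  expect_warning(out <- rtd_slope(c(1, 2, 3), c(0.5, 0.5, 0.5)), "zero variance")
  expect_true(is.na(out))
  # null: slopes centre on zero when time is unrelated to difficulty
  slopes <- withr::with_seed(13, vapply(1:200, function(i) {
    rtd_slope(rnorm(22, 50, 10), runif(22, 0.1, 0.9))
  }, numeric(1)))
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("incomplete-attempt indicators and their decomposition", {
  # 3-rule item with clicks in two rules only
  s <- jump_log(c("a1", "b1"), iid = "it2")
  expect_equal(iap_indicator(s, 3), 1L)
  # all rules touched but the answer wrong: attempt is not correctness
  s <- jump_log(c("a2", "b2", "c3", "c4"), iid = "it2")
  expect_equal(iap_indicator(s, 3), 0L)

  ind <- tibble::tibble(
    participant_id = rep(c("p1", "p2"), each = 4),
    iap = c(1, 0, 0, 1, 0, 0, 0, 1)
  )
  dec <- iap_decompose(ind)
  expect_equal(dec$iap_global, rep(c(0.5, 0.25), each = 4))
  sums <- tapply(dec$iap_current, dec$participant_id, sum)
  expect_lt(max(abs(sums)), 1e-12)
  expect_true(all(dec$iap_global >= 0 & dec$iap_global <= 1))
})

test_that("batch feature extraction agrees with the single-log operations", {
  x <- cached_cohort(3)
  long <- x$features$participant_items
  ev <- tibble::as_tibble(x$cohort$sessions)
  bank22 <- x$cohort$item_bank
  withr::with_seed(4, picks <- sample(nrow(long), 25))
  for (i in picks) {
    one <- ev[ev$participant_id == long$participant_id[i] &
                ev$item_id == long$item_id[i], ]
    nr <- bank22$n_rules[bank22$item_id == long$item_id[i]]
    expect_equal(long$jump_score_item[i], rule_jump_score(one, nr))
    expect_equal(long$iap[i], iap_indicator(one, nr))
    it <- item_times(one, nr)
    expect_equal(long$tot[i], it$tot)
    expect_equal(long$inter[i], it$inter)
    expect_equal(long$intra[i], it$intra)
  }
})
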