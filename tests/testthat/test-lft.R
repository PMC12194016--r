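bank <- tiny_bank()

make_log <- function(clicks_t, clicks_sym, terminal_t = max(clicks_t, 0) + 2,
                     kind = "submit", iid = "it1") {
  ev <- ev_block("p1", iid, clicks_t, clicks_sym, kind, terminal_t)
  as_sessions(ev, bank)
}

test_that("clicks segment by rule in time order", {
  s <- make_log(c(5, 6, 10, 11), c("a1", "a2", "b1", "b2"), 12)
  seg <- segment_by_rule(s)
  expect_equal(seg$rule_id, c("addition", "addition", "subtraction", "subtraction"))
  expect_equal(seg$t, c(5, 6, 10, 11))
  # alternating clicks preserve order
  s <- make_log(c(3, 4, 8), c("a1", "b1", "a2"), 10)
  expect_equal(segment_by_rule(s)$rule_id,
               c("addition", "subtraction", "addition"))
  # instant timeout: no clicks, empty segmentation
  s <- make_log(numeric(0), character(0), 90, kind = "timeout")
  expect_equal(nrow(segment_by_rule(s)), 0L)
})

test_that("item-level times follow the decomposition definitions", {
  s <- make_log(c(5, 6, 10, 11), c("a1", "a2", "b1", "b2"), 12)
  it <- item_times(s, n_rules = 2)
  expect_equal(it$tot, 12)
  expect_equal(it$first_click, 5)
  expect_equal(it$inter_gaps, 4)
  expect_equal(it$intra_gaps, c(1, 1))
  expect_equal(it$inter, 4)  # one transition
  expect_equal(it$intra, 1)

  # every consecutive pair crosses rules: three transitions, no intra pair
  s <- make_log(c(2, 5, 7, 9), c("a1", "b1", "a2", "b2"), 10)
  it <- item_times(s, n_rules = 2)
  expect_equal(it$inter_gaps, c(3, 2, 2))
  expect_equal(length(it$intra_gaps), 0L)
  expect_equal(it$inter, 7 / 3)
  expect_true(is.na(it$intra))
  # alternative denominators
  expect_equal(item_times(s, 2, inter_denominator = "rules")$inter, 7 / 2)
  expect_equal(item_times(s, 2, inter_denominator = "rules1")$inter, 7 / 1)

  # degenerate single click
  s <- make_log(8, "a1", 90, kind = "timeout")
  it <- item_times(s, n_rules = 2)
  expect_equal(it$tot, 90)
  expect_equal(it$first_click, 8)
  expect_equal(it$n_transitions, 0L)
  expect_true(is.na(it$inter) && is.na(it$intra))
})

test_that("the time decomposition identity holds on simulated item logs", {
  co <- cached_cohort(1)$cohort
  ev <- tibble::as_tibble(co$sessions)
  per <- ev |>
    dplyr::group_by(participant_id, item_id) |>
    dplyr::summarise(
      tot = t[kind != "click"][1],
      first = t[kind == "click"][1],
      last = t[kind == "click"][max(1, sum(kind == "click"))],
      gaps = sum(diff(t[kind == "click"])),
      n_clicks = sum(kind == "click"),
      .groups = "drop") |>
    dplyr::filter(n_clicks > 0)
  # first_click + sum(all gaps) + trailing time = ToT
  resid <- per$first + per$gaps + (per$tot - per$last) - per$tot
  expect_lt(max(abs(resid)), 1e-9)
  expect_gte(nrow(per), 1000L)
})

test_that("times are equivariant under a rescaling of the clock", {
  s <- make_log(c(5, 6, 10, 11), c("a1", "a2", "b1", "b2"), 12)
  it1 <- item_times(s, 2)
  s3 <- make_log(3 * c(5, 6, 10, 11), c("a1", "a2", "b1", "b2"), 36)
  it3 <- item_times(s3, 2)
  for (f in c("tot", "first_click", "inter", "intra")) {
    expect_equal(it3[[f]], 3 * it1[[f]])
  }
})

test_that("onset residualization removes the interrule component", {
  withr::with_seed(5, {
    inter <- runif(50, 2, 10)
    # slope-zero limit: predictor unrelated to the response
    fc <- rep(7, 50) + rnorm(50, 0, 1e-6)
    on <- residualize_onset(fc, inter)
    expect_lt(max(abs(on - fc)), 1e-4)
    # perfect collinearity: residual collapses to the recentred mean
    fc2 <- 2 * inter
    on2 <- residualize_onset(fc2, inter)
    expect_equal(on2, rep(mean(fc2), 50), tolerance = 1e-10)
    # orthogonality of the residual to the predictor
    fc3 <- 5 + 0.8 * inter + rnorm(50)
    on3 <- residualize_onset(fc3, inter)
    expect_lt(abs(stats::cor(on3, inter)), 1e-8)
  })
  expect_warning(residualize_onset(c(4, 5, 6), c(2, 2, 2)), "zero variance")
})

test_that("residualized onset tracks the latent onset better than first clicks", {
  wins <- vapply(1:5, function(s) {
    x <- cached_cohort(s)
    m <- merge(x$features$participants, x$cohort$truth$participants,
               by = "participant_id")
    stats::cor(m$onset, m$latent_onset) > stats::cor(m$first_click, m$latent_onset)
  }, logical(1))
  expect_true(all(wins))
})

test_that("participant records average over analysed items", {
  ev <- dplyr::bind_rows(
    ev_block("p1", "it1", c(5, 6, 10, 11), c("a1", "a2", "b1", "b2"), "submit", 12),
    ev_block("p1", "it2", c(4, 10, 18, 19), c("a1", "b1", "c1", "c2"), "submit", 21),
    ev_block("p2", "it1", c(2, 3, 5, 6), c("a1", "a2", "b1", "b2"), "submit", 8),
    ev_block("p2", "it2", c(2, 6, 10, 11), c("a1", "b1", "c1", "c2"), "submit", 13)
  )
  s <- as_sessions(ev, bank)
  lfts <- suppressWarnings(participant_lfts(s, bank))
  expect_equal(nrow(lfts), 2L)
  # p1: it1 inter = 4 (1 transition), it2 inter = (6 + 8) / 2 = 7 -> mean 5.5
  expect_equal(lfts$inter[lfts$participant_id == "p1"], 5.5)
  expect_equal(lfts$tot[lfts$participant_id == "p1"], mean(c(12, 21)))
  expect_equal(lfts$n_items, c(2L, 2L))
  expect_true(all(is.finite(lfts$onset)))
})

test_that("pooled onset residuals are orthogonal to interrule times", {
  long <- attr(participant_lfts(cached_cohort(2)$cohort$sessions), "by_item")
  ok <- is.finite(long$onset) & is.finite(long$inter)
  expect_lt(abs(stats::cor(long$onset[ok], long$inter[ok])), 1e-8)
})
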