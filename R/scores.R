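#' Rule-jump score of one item log
#'
#' A rule jump is a click on a symbol of one rule followed by a click on a
#' symbol of a different rule. The rule-jump score of an item attempt is the
#' number of executed jumps minus the number necessary for the correct
#' solution. The necessary count is `n_rules - 1`: the minimum number of
#' between-rule transitions when every rule's symbols are clicked as one
#' block. The score is negative for abandoned attempts that never visited
#' all rules.
#'
#' @param events event rows of one participant-item.
#' @param n_rules number of rules of the item.
#' @return Integer: executed minus necessary rule jumps.
#' @export
rule_jump_score <- function(events, n_rules) {
  seg <- segment_by_rule(events)
  executed <- if (nrow(seg) < 2) 0L else sum(seg$rule_id[-1] != seg$rule_id[-nrow(seg)])
  as.integer(executed - (n_rules - 1L))
}

#' Total test score of each participant
#'
#' Number of analysed (multi-rule) items solved correctly, i.e. whose final
#' constructed selection equals the solution set exactly.
#'
#' @param sessions an `lft_sessions` tibble.
#' @param item_bank an `lft_item_bank`; defaults to the attached bank.
#' @return A tibble `participant_id`, `score`.
#' @export
test_score <- function(sessions, item_bank = attr(sessions, "item_bank")) {
  out <- item_outcomes(sessions, item_bank)
  out <- out[out$analysis, , drop = FALSE]
  out |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(score = sum(.data$correct), .groups = "drop")
}

#' Classical item statistics
#'
#' Item difficulty `P` (proportion correct), item-rest correlation (Pearson
#' correlation of each item with the total score over the remaining items)
#' and Cronbach's alpha,
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))`.
#'
#' @param correctness binary participants-by-items matrix (or data frame).
#' @return A list of class `lft_item_stats` with a per-item tibble (`item`,
#'   `p`, `r_rest`) and `alpha`. Zero-variance items get `r_rest = NA` with a
#'   warning; a single-item matrix is an error (alpha needs `k >= 2`).
#' @export
item_stats <- function(correctness) {
  x <- as.matrix(correctness)
  if (ncol(x) < 2L) abort("alpha requires at least 2 items")
  if (nrow(x) < 2L) abort("need at least 2 participants")
  total <- rowSums(x)
  p <- colMeans(x)
  r_rest <- vapply(seq_len(ncol(x)), function(j) {
    rest <- total - x[, j]
    if (stats::sd(x[, j]) == 0 || stats::sd(rest) == 0) NA_real_
    else stats::cor(x[, j], rest)
  }, numeric(1))
  if (anyNA(r_rest)) warn("zero-variance item(s): item-rest correlation undefined")
  k <- ncol(x)
  alpha <- k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / stats::var(total))
  structure(list(
    items = tibble::tibble(item = colnames(x) %||% as.character(seq_len(k)),
                           p = unname(p), r_rest = r_rest),
    alpha = alpha
  ), class = "lft_item_stats")
}

#' @export
print.lft_item_stats <- function(x, ...) {
  cat(sprintf("<lft_item_stats> %d items, mean P = %.2f, alpha = %.2f\n",
              nrow(x$items), mean(x$items$p), x$alpha))
  invisible(x)
}

#' Acceleration across the test (first third minus last third)
#'
#' Practice-related speed-up of a per-item time series: the mean over the
#' first `floor(n/3)` items minus the mean over the last `floor(n/3)` items
#' (middle discarded; thirds of 7 items for a 22-item test). Decreasing
#' times give a positive value ("accelerating").
#'
#' @param values numeric vector of per-item values in test position order;
#'   `NA`s are ignored within each third.
#' @return The mean difference (delta-M).
#' @export
acceleration <- function(values) {
  n <- length(values)
  if (n < 3L) abort("acceleration needs at least 3 items")
  third <- n %/% 3L
  mean(values[seq_len(third)], na.rm = TRUE) -
    mean(values[seq.int(n - third + 1L, n)], na.rm = TRUE)
}

#' Response-to-difficulty slope of one participant
#'
#' Intraindividual regression slope of item response time on item
#' difficulty; higher slopes indicate greater willingness to invest time in
#' harder items. By default both variables are z-standardized within the
#' participant, so the slope equals the correlation and is comparable across
#' participants; `standardized = FALSE` gives the raw seconds-per-difficulty
#' slope.
#'
#' @param tot per-item response times of one participant.
#' @param difficulty matched item difficulties (conventionally `1 - P` with
#'   `P` estimated from the analysed sample).
#' @param standardized z-score both variables first (default `TRUE`).
#' @return The slope; `NA` with a warning when the difficulty (or time)
#'   variance is zero. Fewer than 3 complete items is an error.
#' @export
rtd_slope <- function(tot, difficulty, standardized = TRUE) {
  ok <- is.finite(tot) & is.finite(difficulty)
  if (sum(ok) < 3L) abort("response-to-difficulty slope needs at least 3 items")
  tot <- tot[ok]; difficulty <- difficulty[ok]
  if (stats::sd(difficulty) == 0 || (standardized && stats::sd(tot) == 0)) {
    warn("zero variance: response-to-difficulty slope undefined")
    return(NA_real_)
  }
  if (standardized) {
    stats::cor(tot, difficulty)
  } else {
    unname(stats::coef(stats::lm(tot ~ difficulty))[2])
  }
}

#' Incomplete-attempt indicator of one item log
#'
#' An attempt of a rule is at least one click on a symbol of that rule's
#' group. The indicator is 1 when the item terminated with fewer attempted
#' rules than the item contains (the participant gave up before working all
#' rules), 0 otherwise. Attempt is independent of correctness.
#'
#' @param events event rows of one participant-item.
#' @param n_rules number of rules of the item.
#' @return 0/1 integer.
#' @export
iap_indicator <- function(events, n_rules) {
  seg <- segment_by_rule(events)
  as.integer(length(unique(seg$rule_id)) < n_rules)
}

#' Decompose incomplete-attempt indicators into global and current parts
#'
#' The global IAP of a participant is the mean indicator over items (their
#' general tendency to leave items incomplete, in `[0, 1]`); the current IAP
#' is the group-mean-centred per-item indicator (occasional lapses), which
#' sums to zero within every participant.
#'
#' @param indicators long tibble with columns `participant_id` and `iap`
#'   (0/1 per participant-item).
#' @return The input with columns `iap_global` and `iap_current` added.
#' @export
iap_decompose <- function(indicators) {
  indicators |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(iap_global = mean(.data$iap),
                  iap_current = .data$iap - mean(.data$iap)) |>
    dplyr::ungroup()
}
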