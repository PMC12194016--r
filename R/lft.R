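#' Segment the clicks of one item log by rule
#'
#' Maps every click of a single participant-item stream to the rule its
#' symbol belongs to, preserving time order; terminal events are dropped.
#' Consecutive entries with different rules are rule transitions, the raw
#' material of both the interrule times and the rule-jump score.
#'
#' @param events event rows of one participant-item (with `rule_id`
#'   annotated, as produced by [read_event_log()] / [as_sessions()]).
#' @return A tibble with columns `rule_id` and `t`, one row per click.
#' @export
segment_by_rule <- function(events) {
  clicks <- events[events$kind == "click", , drop = FALSE]
  if (any(is.na(clicks$rule_id))) abort("click with unmappable symbol")
  tibble::tibble(rule_id = clicks$rule_id, t = clicks$t)
}

#' Time decomposition of one item log
#'
#' Decomposes a single participant-item click stream into its temporal
#' components: `tot` is the terminal-event time, `first_click` the time of
#' the first click, `inter_gaps` the gaps between consecutive clicks on
#' *different* rules, `intra_gaps` the gaps between consecutive clicks on the
#' *same* rule. The components satisfy the exact identity
#' `first_click + sum(inter_gaps) + sum(intra_gaps) + (tot - last_click) = tot`.
#'
#' The item-level interrule time divides the summed between-rule gaps by a
#' configurable denominator: `"transitions"` (the observed number of
#' between-rule transitions; the default, since it is the only choice
#' invariant to rule-jump inflation of the transition count), `"rules"`, or
#' `"rules1"` (number of rules minus one, the minimum transition count).
#' The item-level intrarule time is the mean within-rule gap.
#'
#' @param events event rows of one participant-item.
#' @param n_rules number of rules of the item (for the rule-based
#'   denominators).
#' @param inter_denominator one of `"transitions"`, `"rules"`, `"rules1"`.
#' @return A list with `tot`, `first_click`, `last_click`, `inter_gaps`,
#'   `intra_gaps`, `n_transitions`, `inter`, `intra`. Items without clicks
#'   have `first_click = NA` and contribute ToT only; items without a
#'   same-rule click pair have `intra = NA`.
#' @export
item_times <- function(events, n_rules,
                       inter_denominator = c("transitions", "rules", "rules1")) {
  inter_denominator <- match.arg(inter_denominator)
  seg <- segment_by_rule(events)
  term <- events[events$kind != "click", , drop = FALSE]
  if (nrow(term) != 1L) abort("item log must contain exactly one terminal event")
  tot <- term$t
  n <- nrow(seg)
  if (n == 0L) {
    return(list(tot = tot, first_click = NA_real_, last_click = NA_real_,
                inter_gaps = numeric(0), intra_gaps = numeric(0),
                n_transitions = 0L, inter = NA_real_, intra = NA_real_))
  }
  gaps <- diff(seg$t)
  same <- seg$rule_id[-1] == seg$rule_id[-n]
  inter_gaps <- gaps[!same]
  intra_gaps <- gaps[same]
  denom <- switch(inter_denominator,
                  transitions = length(inter_gaps),
                  rules = n_rules,
                  rules1 = n_rules - 1L)
  list(
    tot = tot, first_click = seg$t[1], last_click = seg$t[n],
    inter_gaps = inter_gaps, intra_gaps = intra_gaps,
    n_transitions = length(inter_gaps),
    inter = if (denom > 0 && length(inter_gaps)) sum(inter_gaps) / denom else NA_real_,
    intra = if (length(intra_gaps)) mean(intra_gaps) else NA_real_
  )
}

#' Residualize the first-click time into an onset time
#'
#' The time before the first click confounds the global orientation onset
#' with the planning time of the first rule. The onset time is therefore
#' defined as the residual of a pooled ordinary least squares regression
#' across all participant-items, recentred by the grand mean first-click
#' time so that it keeps the seconds scale and a positive mean.
#'
#' With the default direction the first-click time is the response and the
#' item's interrule time the predictor (`"first_on_inter"`), which purges the
#' rule-planning component from the first-click time. The literal alternative
#' `"inter_on_first"` (residuals of interrule regressed on first-click,
#' recentred the same way) is available as a switch.
#'
#' @param first_click numeric vector over participant-items.
#' @param inter matched numeric vector of item-level interrule times.
#' @param direction `"first_on_inter"` (default) or `"inter_on_first"`.
#' @return Numeric vector of onset times, `NA` where either input is missing.
#'   If the predictor has zero variance the residualization degenerates to
#'   centring (with a warning), i.e. the first-click times are returned.
#' @export
residualize_onset <- function(first_click, inter,
                              direction = c("first_on_inter", "inter_on_first")) {
  direction <- match.arg(direction)
  if (length(first_click) != length(inter)) abort("vectors must be aligned")
  ok <- is.finite(first_click) & is.finite(inter)
  if (sum(ok) < 3L) abort("need at least 3 complete participant-items")
  y <- if (direction == "first_on_inter") first_click else inter
  x <- if (direction == "first_on_inter") inter else first_click
  centre <- mean(first_click[ok])
  res <- rep(NA_real_, length(first_click))
  if (stats::sd(x[ok]) == 0) {
    warn("zero variance in the residualization predictor; degenerating to centring")
    res[ok] <- y[ok] - mean(y[ok])
  } else {
    fit <- stats::lm(y[ok] ~ x[ok])
    res[ok] <- stats::resid(fit)
  }
  res + centre
}

#' Per participant-item log-file times
#'
#' Applies [item_times()] to every participant-item of the analysis set
#' (items with at least two rules) and adds the residualized onset time
#' ([residualize_onset()], pooled over all participant-items).
#'
#' @param sessions an `lft_sessions` tibble.
#' @param item_bank an `lft_item_bank`; defaults to the attached bank.
#' @param inter_denominator see [item_times()].
#' @param onset_direction see [residualize_onset()].
#' @return A tibble with one row per participant and analysis item:
#'   `participant_id`, `item_id`, `position`, `tot`, `first_click`, `onset`,
#'   `inter`, `intra`, `n_transitions`, `n_inter_gaps`, `n_intra_gaps`.
#' @export
participant_item_lfts <- function(sessions,
                                  item_bank = attr(sessions, "item_bank"),
                                  inter_denominator = c("transitions", "rules", "rules1"),
                                  onset_direction = c("first_on_inter", "inter_on_first")) {
  inter_denominator <- match.arg(inter_denominator)
  onset_direction <- match.arg(onset_direction)
  stopifnot(inherits(item_bank, "lft_item_bank"))
  keep_items <- item_bank$item_id[item_bank$analysis]
  ev <- tibble::as_tibble(sessions)
  ev <- ev[ev$item_id %in% keep_items, , drop = FALSE]
  meta <- tibble::as_tibble(item_bank[c("item_id", "position", "n_rules")])

  # vectorized equivalent of applying item_times() per participant-item
  terminals <- ev[ev$kind != "click", c("participant_id", "item_id", "t")]
  names(terminals)[3] <- "tot"
  clicks <- ev[ev$kind == "click", , drop = FALSE] |>
    dplyr::group_by(.data$participant_id, .data$item_id) |>
    dplyr::mutate(gap = .data$t - dplyr::lag(.data$t),
                  same = .data$rule_id == dplyr::lag(.data$rule_id)) |>
    dplyr::summarise(
      first_click = .data$t[1],
      last_click = .data$t[dplyr::n()],
      n_transitions = sum(!.data$same, na.rm = TRUE),
      sum_inter = sum(.data$gap[!.data$same], na.rm = TRUE),
      n_intra_gaps = sum(.data$same, na.rm = TRUE),
      sum_intra = sum(.data$gap[.data$same], na.rm = TRUE),
      n_rules_touched = dplyr::n_distinct(.data$rule_id),
      .groups = "drop"
    )
  long <- terminals |>
    dplyr::left_join(clicks, by = c("participant_id", "item_id")) |>
    dplyr::left_join(meta, by = "item_id")
  long$n_transitions[is.na(long$n_transitions)] <- 0L
  long$n_rules_touched[is.na(long$n_rules_touched)] <- 0L
  denom <- switch(inter_denominator,
                  transitions = long$n_transitions,
                  rules = long$n_rules,
                  rules1 = long$n_rules - 1L)
  long$inter <- ifelse(long$n_transitions > 0 & denom > 0,
                       long$sum_inter / denom, NA_real_)
  long$intra <- ifelse(!is.na(long$n_intra_gaps) & long$n_intra_gaps > 0,
                       long$sum_intra / long$n_intra_gaps, NA_real_)
  long <- long[order(long$participant_id, long$position), ]
  if (sum(is.finite(long$first_click) & is.finite(long$inter)) >= 3) {
    long$onset <- residualize_onset(long$first_click, long$inter, onset_direction)
  } else {
    warn("too few participant-items to residualize; onset = first-click time")
    long$onset <- long$first_click
  }
  long[c("participant_id", "item_id", "position", "n_rules", "tot", "first_click",
         "last_click", "onset", "inter", "intra", "n_transitions",
         "n_intra_gaps", "n_rules_touched")]
}

#' Per-participant log-file time records
#'
#' Aggregates [participant_item_lfts()] to one record per participant: the
#' mean ToT, first-click, onset, interrule and intrarule time over the
#' analysed items. Items contributing no interrule or intrarule value (no
#' transition, or no same-rule click pair) are simply excluded from that
#' mean; participants with no analysable item are dropped with a warning.
#'
#' @inheritParams participant_item_lfts
#' @return A tibble with one row per participant: `participant_id`, `tot`,
#'   `first_click`, `onset`, `inter`, `intra`, `n_items`. The per-item table
#'   is attached as `attr(, "by_item")`.
#' @export
participant_lfts <- function(sessions,
                             item_bank = attr(sessions, "item_bank"),
                             inter_denominator = c("transitions", "rules", "rules1"),
                             onset_direction = c("first_on_inter", "inter_on_first")) {
  long <- participant_item_lfts(sessions, item_bank,
                                inter_denominator, onset_direction)
  agg <- long |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      tot = mean(.data$tot, na.rm = TRUE),
      first_click = mean(.data$first_click, na.rm = TRUE),
      onset = mean(.data$onset, na.rm = TRUE),
      inter = mean(.data$inter, na.rm = TRUE),
      intra = mean(.data$intra, na.rm = TRUE),
      n_items = dplyr::n(),
      .groups = "drop"
    )
  empty <- agg$n_items == 0
  if (any(empty)) {
    warn(sprintf("excluding %d participant(s) without analysable items", sum(empty)))
    agg <- agg[!empty, , drop = FALSE]
  }
  attr(agg, "by_item") <- long
  agg
}
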