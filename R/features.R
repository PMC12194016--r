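#' Build the full per-participant feature table
#'
#' Runs the complete feature-extraction stage on a validated session table:
#' log-file times ([participant_lfts()]), test score, rule-jump score,
#' acceleration of every time component over the test
#' ([acceleration()]), response-to-difficulty slope ([rtd_slope()], with item
#' difficulty `1 - P` estimated from the sample) and the incomplete-attempt
#' propensity decomposition ([iap_decompose()]).
#'
#' @param sessions an `lft_sessions` tibble.
#' @param item_bank an `lft_item_bank`; defaults to the attached bank.
#' @param inter_denominator see [item_times()].
#' @param onset_direction see [residualize_onset()].
#' @param rtd_standardized see [rtd_slope()].
#' @return A list of class `lft_features`:
#'   * `participants`: one row per participant with `score`, `tot`,
#'     `first_click`, `onset`, `inter`, `intra`, `jump_score`,
#'     `accel_tot`, `accel_onset`, `accel_inter`, `accel_intra`,
#'     `rtd_slope`, `iap_global`;
#'   * `participant_items`: the long per participant-item table (times,
#'     per-item jump score, `iap`, `iap_current`, `correct`);
#'   * `item_stats`: per-item summary (`n_rules`, `p`, `r_rest`, mean `tot`,
#'     `onset`, `inter`, `intra`) plus Cronbach's `alpha` as an attribute.
#' @export
participant_features <- function(sessions,
                                 item_bank = attr(sessions, "item_bank"),
                                 inter_denominator = c("transitions", "rules", "rules1"),
                                 onset_direction = c("first_on_inter", "inter_on_first"),
                                 rtd_standardized = TRUE) {
  stopifnot(inherits(item_bank, "lft_item_bank"))
  lfts <- participant_lfts(sessions, item_bank,
                           inter_denominator = inter_denominator,
                           onset_direction = onset_direction)
  by_item <- attr(lfts, "by_item")
  outcomes <- item_outcomes(sessions, item_bank)
  outcomes <- outcomes[outcomes$analysis, , drop = FALSE]

  # per-item rule-jump score and incomplete-attempt indicator: the transition
  # and touched-rule counts of the vectorized extraction are exactly the
  # executed-jump count and attempted-rule count of rule_jump_score() /
  # iap_indicator()
  long <- by_item
  long$jump_score_item <- long$n_transitions - (long$n_rules - 1L)
  long$iap <- as.integer(long$n_rules_touched < long$n_rules)
  long <- iap_decompose(long)
  long <- dplyr::left_join(long,
                           outcomes[c("participant_id", "item_id", "correct")],
                           by = c("participant_id", "item_id"))

  # sample-estimated item difficulty for the response-to-difficulty slope
  p_item <- outcomes |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(p = mean(.data$correct), .groups = "drop")
  long <- dplyr::left_join(long, p_item, by = "item_id")
  long$item_difficulty <- 1 - long$p
  long$p <- NULL

  per_part <- long |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::summarise(
      score = sum(.data$correct),
      jump_score = mean(.data$jump_score_item),
      accel_tot = acceleration(.data$tot),
      accel_onset = acceleration(.data$onset),
      accel_inter = acceleration(.data$inter),
      accel_intra = acceleration(.data$intra),
      rtd_slope = rtd_slope(.data$tot, .data$item_difficulty,
                            standardized = rtd_standardized),
      iap_global = mean(.data$iap),
      .groups = "drop"
    )
  participants <- dplyr::left_join(lfts, per_part, by = "participant_id")
  attr(participants, "by_item") <- NULL

  stats <- item_feature_stats(long, outcomes, item_bank)
  structure(list(participants = participants,
                 participant_items = long,
                 item_stats = stats),
            class = "lft_features")
}

# Table of per-item characteristics: rules, difficulty, item-rest
# correlation and mean time components; alpha attached as attribute.
item_feature_stats <- function(long, outcomes, item_bank) {
  wide <- outcomes |>
    dplyr::select("participant_id", "item_id", "correct") |>
    tidyr::pivot_wider(names_from = "item_id", values_from = "correct")
  mat <- as.matrix(wide[, -1, drop = FALSE]) * 1L
  ist <- withCallingHandlers(item_stats(mat),
                             warning = function(w) invokeRestart("muffleWarning"))
  times <- long |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(
      m_tot = mean(.data$tot, na.rm = TRUE),
      m_onset = mean(.data$onset, na.rm = TRUE),
      m_inter = mean(.data$inter, na.rm = TRUE),
      m_intra = mean(.data$intra, na.rm = TRUE),
      .groups = "drop"
    )
  tab <- tibble::tibble(item_id = ist$items$item,
                        p = ist$items$p, r_rest = ist$items$r_rest) |>
    dplyr::left_join(tibble::as_tibble(item_bank[c("item_id", "position", "n_rules")]),
                     by = "item_id") |>
    dplyr::left_join(times, by = "item_id") |>
    dplyr::arrange(.data$position)
  tab <- tab[c("item_id", "position", "n_rules", "p", "r_rest",
               "m_tot", "m_onset", "m_inter", "m_intra")]
  attr(tab, "alpha") <- ist$alpha
  tab
}

#' @export
print.lft_features <- function(x, ...) {
  cat(sprintf("<lft_features> %d participants, %d analysed items (alpha = %.2f)\n",
              nrow(x$participants), nrow(x$item_stats),
              attr(x$item_stats, "alpha")))
  invisible(x)
}
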