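#' Configuration for the synthetic cohort generator
#'
#' Parameterizes a generative model for click streams of a construction-based
#' matrix test. The cohort is a two-class mixture of *structured* processors
#' (who plan each rule, reflected in long interrule gaps that shorten with
#' ability and with practice) and *unstructured* processors (short gaps, many
#' rule jumps). All duration components are log-normal: response-time
#' components are positive and right-skewed, and only their location/scale
#' matters for the downstream statistics.
#'
#' Couplings plant the statistical structure the analysis pipeline is meant
#' to recover: `ability_coupling` (ability shortens interrule gaps within the
#' structured class), `practice_decline_ability` (the practice-related decline
#' of interrule gaps grows with ability, structured class only),
#' `coupling$intra` (slower planners also execute more slowly),
#' `coupling$jumps_gap` (gap length modulates the Poisson rate of rule-jump
#' excursions), and `coupling$jump_failure` (each excursion lowers the
#' log-odds of solving a rule). Response-to-difficulty is planted by scaling
#' an item's whole time budget with `1 + rtd_slope * z(difficulty)`, and
#' incomplete attempts (IAP) by abandoning an item before all rules with a
#' Beta-distributed per-participant propensity, which leaves the item to time
#' out at the limit.
#'
#' @param n_participants cohort size (default 200).
#' @param p_structured mixture weight of the structured class (default 0.56).
#' @param ability list of `c(mean, sd)` per class; defaults
#'   `structured = c(0.8, 0.8)`, `unstructured = c(-0.8, 0.8)`.
#' @param rule_difficulty `c(mean, sd)` of per-rule difficulties on the
#'   logit scale (default `c(0.5, 0.5)`).
#' @param onset log-normal onset component: `meanlog`, `sdlog`,
#'   `participant_sd` (between-person SD on meanlog), `practice_decline`
#'   (meanlog decrease per test position).
#' @param interrule interrule planning gaps: class-specific `meanlog`,
#'   shared `sdlog` and `participant_sd`, `ability_coupling` (subtracted
#'   times ability from the structured meanlog), `practice_decline` (baseline
#'   meanlog decrease per position) and `practice_decline_ability` (added
#'   times ability, structured class only).
#' @param intrarule within-rule click gaps: `meanlog`, `sdlog`,
#'   `participant_sd`.
#' @param coupling list with `intra`, `jumps_base` (per-class log baseline of
#'   the excursion Poisson rate), `jumps_gap`, `jump_failure` (see above).
#' @param success_intercept intercept of the rule-success link
#'   `P(solved) = plogis(success_intercept + ability - difficulty -
#'   jump_failure * excursions)`; calibrates the overall success level of the
#'   cohort (default 1.0).
#' @param excursion log-normal gap for each click of a rule-jump excursion.
#' @param review log-normal gap between the last click and the submit event.
#' @param rtd `c(mean, sd)` of the per-participant response-to-difficulty
#'   multiplier slope.
#' @param iap `c(shape1, shape2)` of the Beta distribution of the
#'   per-participant incomplete-attempt propensity.
#' @param time_limit item time limit in seconds (default 90); events beyond
#'   it are censored and the item times out. May be `Inf` to disable
#'   censoring.
#' @param seed default seed used by [generate_cohort()].
#' @return A validated `lft_generator_config` list.
#' @export
generator_config <- function(n_participants = 200,
                             p_structured = 0.56,
                             ability = list(structured = c(mean = 0.8, sd = 0.8),
                                            unstructured = c(mean = -0.8, sd = 0.8)),
                             rule_difficulty = c(mean = 0.5, sd = 0.5),
                             onset = list(meanlog = log(14), sdlog = 0.4,
                                          participant_sd = 0.25, practice_decline = 0.05),
                             interrule = list(meanlog = c(structured = log(18),
                                                          unstructured = log(2.5)),
                                              sdlog = 0.40, participant_sd = 0.20,
                                              ability_coupling = 0.20,
                                              practice_decline = 0.006,
                                              practice_decline_ability = 0.015),
                             intrarule = list(meanlog = log(1.1), sdlog = 0.4,
                                              participant_sd = 0.15),
                             coupling = list(intra = 0.25,
                                             jumps_base = c(structured = -0.7,
                                                            unstructured = 1.3),
                                             jumps_gap = 0.35,
                                             jump_failure = 0.15),
                             success_intercept = 1.15,
                             excursion = list(meanlog = log(0.7), sdlog = 0.4),
                             review = list(meanlog = log(2.5), sdlog = 0.3),
                             rtd = c(mean = 0.25, sd = 0.25),
                             iap = c(shape1 = 0.3, shape2 = 12),
                             time_limit = 90,
                             seed = NULL) {
  cfg <- list(
    n_participants = n_participants, p_structured = p_structured,
    ability = ability, rule_difficulty = rule_difficulty, onset = onset,
    interrule = interrule, intrarule = intrarule, coupling = coupling,
    success_intercept = success_intercept,
    excursion = excursion, review = review, rtd = rtd, iap = iap,
    time_limit = time_limit, seed = seed
  )
  class(cfg) <- "lft_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  assert_number(cfg$n_participants, "n_participants", lower = 1)
  assert_number(cfg$p_structured, "p_structured", lower = 0, upper = 1)
  for (cl in c("structured", "unstructured")) {
    if (cfg$ability[[cl]][["sd"]] <= 0) abort("ability sd must be > 0")
  }
  if (cfg$rule_difficulty[["sd"]] <= 0) abort("rule difficulty sd must be > 0")
  for (comp in c("onset", "interrule", "intrarule", "excursion", "review")) {
    if (cfg[[comp]]$sdlog <= 0) abort(sprintf("%s sdlog must be > 0", comp))
  }
  if (any(cfg$iap <= 0)) abort("iap Beta shapes must be > 0")
  if (!(is.numeric(cfg$time_limit) && cfg$time_limit > 0)) {
    abort("time_limit must be > 0")
  }
  invisible(cfg)
}

#' Generate a synthetic cohort of matrix-test sessions
#'
#' Simulates, participant by participant and item by item (in test position
#' order), the full click stream of a construction-based matrix test with the
#' generative model described in [generator_config()], and returns the event
#' log together with the complete ground truth of every latent quantity —
#' class membership, ability, latent time components, response-to-difficulty
#' slope, incomplete-attempt propensity and per-rule difficulties — so that
#' recovery of planted structure can be tested downstream.
#'
#' The first click of an item occurs at `onset + first planning gap`, so the
#' observable first-click time confounds the orientation onset with the first
#' rule's planning time; the residualization in [residualize_onset()] is
#' designed to undo exactly this confound. Rule-jump excursions revisit the
#' symbol group of a previously processed rule (one click, immediately
#' toggled back), perturbing jump counts and transition counts without
#' changing the final selection. All events past the time limit are censored
#' and replaced by a timeout terminal.
#'
#' @param config an [generator_config()] object.
#' @param item_bank the item bank to simulate on (default
#'   [default_item_bank()]); its time limits are overridden by
#'   `config$time_limit`.
#' @param seed integer seed; defaults to `config$seed`. The same seed yields
#'   a byte-identical cohort.
#' @return A list of class `lft_cohort` with elements `sessions` (validated
#'   `lft_sessions` event tibble), `truth` (list of `participants` and
#'   `items` ground-truth tibbles) and `item_bank`.
#' @export
generate_cohort <- function(config = generator_config(),
                            item_bank = default_item_bank(),
                            seed = config$seed) {
  validate_generator_config(config)
  if (is.null(seed)) abort("a seed is required (pass `seed` or set it in the config)")
  withr::with_seed(as.integer(seed), generate_cohort_impl(config, item_bank))
}

generate_cohort_impl <- function(cfg, bank) {
  n <- as.integer(cfg$n_participants)
  bank$time_limit <- rep(cfg$time_limit, nrow(bank))
  limit <- cfg$time_limit
  groups <- attr(bank, "symbol_groups")

  ## ---- participant latents -------------------------------------------------
  cls <- ifelse(runif(n) < cfg$p_structured, "structured", "unstructured")
  theta <- ifelse(cls == "structured",
                  rnorm(n, cfg$ability$structured[["mean"]], cfg$ability$structured[["sd"]]),
                  rnorm(n, cfg$ability$unstructured[["mean"]], cfg$ability$unstructured[["sd"]]))
  eps_onset <- rnorm(n, 0, cfg$onset$participant_sd)
  eps_gap <- rnorm(n, 0, cfg$interrule$participant_sd)
  eps_intra <- rnorm(n, 0, cfg$intrarule$participant_sd)
  rho <- rnorm(n, cfg$rtd[["mean"]], cfg$rtd[["sd"]])
  pi_iap <- rbeta(n, cfg$iap[["shape1"]], cfg$iap[["shape2"]])

  mu_gap0 <- cfg$interrule$meanlog[cls] +
    ifelse(cls == "structured", -cfg$interrule$ability_coupling * theta, 0) +
    eps_gap
  delta_gap <- pmax(0, cfg$interrule$practice_decline +
    ifelse(cls == "structured", cfg$interrule$practice_decline_ability * theta, 0))
  latent_gap <- exp(mu_gap0 + cfg$interrule$sdlog^2 / 2)
  # couplings act on the within-class z-score of the latent mean gap
  z_gap <- stats::ave(latent_gap, cls, FUN = function(x) {
    if (length(x) < 2 || stats::sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / stats::sd(x)
  })
  intra_scale <- pmax(0.2, 1 + cfg$coupling$intra * z_gap)
  lambda_jump <- exp(cfg$coupling$jumps_base[cls] + cfg$coupling$jumps_gap * z_gap)

  ## ---- item latents --------------------------------------------------------
  rule_diff <- purrr::map(bank$rules, function(r) {
    setNames(rnorm(nrow(r), cfg$rule_difficulty[["mean"]], cfg$rule_difficulty[["sd"]]),
             r$rule_id)
  })
  diff_index <- vapply(rule_diff, mean, numeric(1)) + 0.15 * (bank$n_rules - 2)
  z_diff <- zstd(diff_index, allow_const = TRUE)

  pid <- sprintf("p%03d", seq_len(n))
  n_items <- nrow(bank)
  ev <- vector("list", n * n_items)
  k <- 0L

  for (i in seq_len(n)) {
    for (j in seq_len(n_items)) {
      pos <- bank$position[j]
      rules <- bank$rules[[j]]
      sol <- bank$solution[[j]]
      lookup <- bank$symbol_rule[[j]]
      R <- nrow(rules)
      m_ij <- max(0.2, 1 + rho[i] * z_diff[j])

      # incomplete attempt: abandon before processing all rules
      n_att <- R
      if (R >= 2 && runif(1) < pi_iap[i]) n_att <- sample.int(R - 1, 1)

      n_exc <- rpois(1, lambda_jump[i])
      t_click <- numeric(0)
      s_click <- character(0)
      t_now <- rlnorm(1, cfg$onset$meanlog + eps_onset[i] -
                        cfg$onset$practice_decline * (pos - 1), cfg$onset$sdlog) * m_ij
      # spread the excursions over the attempted rules (none before rule 2:
      # an excursion revisits a previously processed rule's group)
      exc_per_rule <- rep(0L, R)
      if (n_exc > 0 && n_att >= 2) {
        targets <- 1L + sample.int(n_att - 1L, n_exc, replace = TRUE)
        exc_per_rule <- tabulate(targets, nbins = R)
      }

      for (r in seq_len(n_att)) {
        gap <- rlnorm(1, mu_gap0[i] - delta_gap[i] * (pos - 1), cfg$interrule$sdlog) * m_ij
        rule_syms <- sol[lookup[sol] == rules$rule_id[r]]
        solved <- runif(1) < plogis(cfg$success_intercept + theta[i] -
                                      rule_diff[[j]][[rules$rule_id[r]]] -
                                      cfg$coupling$jump_failure * n_exc)
        picks <- rule_syms
        if (!solved) {
          # click a wrong symbol of the same group instead of a correct one
          group_syms <- groups[[rules$symbol_group[r]]]
          wrong <- setdiff(group_syms, rule_syms)
          if (length(wrong)) picks[1] <- wrong[1] else picks <- picks[-1]
        }
        n_picks <- length(picks)
        gaps <- c(gap, if (n_picks > 1)
          rlnorm(n_picks - 1, cfg$intrarule$meanlog + eps_intra[i],
                 cfg$intrarule$sdlog) * intra_scale[i] * m_ij)
        tt <- t_now + cumsum(gaps)
        t_click <- c(t_click, tt)
        s_click <- c(s_click, picks)
        t_now <- tt[n_picks]
        # rule-jump excursions after this rule: revisit an earlier rule's group
        if (exc_per_rule[r] > 0) {
          for (x in seq_len(exc_per_rule[r])) {
            back <- sample.int(r - 1, 1)
            back_syms <- groups[[rules$symbol_group[back]]]
            sym <- back_syms[sample.int(length(back_syms), 1)]
            g2 <- rlnorm(2, cfg$excursion$meanlog, cfg$excursion$sdlog)
            t_click <- c(t_click, t_now + g2[1], t_now + g2[1] + g2[2])
            s_click <- c(s_click, sym, sym)
            t_now <- t_now + g2[1] + g2[2]
          }
        }
      }

      # censoring and terminal event
      keep <- t_click <= limit
      censored <- any(!keep)
      t_click <- t_click[keep]
      s_click <- s_click[keep]
      if (n_att < R && is.finite(limit)) {
        term_kind <- "timeout"; term_t <- limit
      } else if (censored) {
        term_kind <- "timeout"; term_t <- limit
      } else {
        term_t <- t_now + rlnorm(1, cfg$review$meanlog, cfg$review$sdlog)
        if (term_t > limit) {
          term_kind <- "timeout"; term_t <- limit
        } else term_kind <- "submit"
      }

      k <- k + 1L
      ev[[k]] <- list(
        participant_id = rep(pid[i], length(t_click) + 1L),
        item_id = rep(bank$item_id[j], length(t_click) + 1L),
        t = c(t_click, term_t),
        kind = c(rep("click", length(t_click)), term_kind),
        symbol_id = c(s_click, NA_character_)
      )
    }
  }

  events <- tibble::tibble(
    participant_id = unlist(lapply(ev, `[[`, "participant_id")),
    item_id = unlist(lapply(ev, `[[`, "item_id")),
    t = unlist(lapply(ev, `[[`, "t")),
    kind = unlist(lapply(ev, `[[`, "kind")),
    symbol_id = unlist(lapply(ev, `[[`, "symbol_id"))
  )
  sessions <- as_sessions(events, bank)

  truth_participants <- tibble::tibble(
    participant_id = pid, class = cls, theta = theta,
    latent_onset = exp(cfg$onset$meanlog + eps_onset + cfg$onset$sdlog^2 / 2),
    latent_gap = latent_gap,
    latent_intra = exp(cfg$intrarule$meanlog + eps_intra +
                         cfg$intrarule$sdlog^2 / 2) * intra_scale,
    gap_decline = delta_gap, jump_rate = lambda_jump,
    rtd_slope = rho, iap_propensity = pi_iap
  )
  truth_items <- tibble::tibble(
    item_id = bank$item_id, position = bank$position, n_rules = bank$n_rules,
    difficulty = diff_index, rule_difficulties = rule_diff
  )
  structure(list(sessions = sessions,
                 truth = list(participants = truth_participants, items = truth_items),
                 item_bank = bank),
            class = "lft_cohort")
}

#' Per-class summary of generator ground truth
#'
#' Debugging aid: means of every latent per simulated class.
#'
#' @param truth the `truth` element of a [generate_cohort()] result (or the
#'   cohort itself).
#' @return A tibble with one row per class and the count and mean of each
#'   latent; zero rows for an empty cohort.
#' @export
summarize_truth <- function(truth) {
  if (inherits(truth, "lft_cohort")) truth <- truth$truth
  tp <- truth$participants
  if (is.null(tp) || nrow(tp) == 0) {
    return(tibble::tibble(class = character(), n = integer()))
  }
  tp |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::where(is.numeric), mean),
      .groups = "drop"
    )
}

#' @export
print.lft_cohort <- function(x, ...) {
  cat(sprintf("<lft_cohort> %d participants x %d items, %d events\n",
              nrow(x$truth$participants), nrow(x$item_bank), nrow(x$sessions)))
  invisible(x)
}
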