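# Fixtures built in code: a small item bank, event-stream builders, and a
# session-scoped cache of default synthetic cohorts.

tiny_bank_json <- function(extra_items = list()) {
  doc <- list(
    symbol_groups = list(
      gA = c("a1", "a2", "a3", "a4"),
      gB = c("b1", "b2", "b3", "b4"),
      gC = c("c1", "c2", "c3", "c4")
    ),
    items = c(list(
      list(item_id = "it1", position = 1, time_limit = 90,
           rules = list(
             list(rule_id = "addition", symbol_group = "gA", n_required_clicks = 2),
             list(rule_id = "subtraction", symbol_group = "gB", n_required_clicks = 1)
           ),
           solution = list("a1", "a2", "b1")),
      list(item_id = "it2", position = 2, time_limit = 90,
           rules = list(
             list(rule_id = "rotation", symbol_group = "gA", n_required_clicks = 1),
             list(rule_id = "intersection", symbol_group = "gB", n_required_clicks = 1),
             list(rule_id = "completeness", symbol_group = "gC", n_required_clicks = 2)
           ),
           solution = list("a1", "b1", "c1", "c2"))
    ), extra_items)
  )
  path <- withr::local_tempfile(fileext = ".json", .local_envir = parent.frame())
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

tiny_bank <- function(...) read_item_bank(tiny_bank_json(...))

# one participant-item event block
ev_block <- function(pid, iid, clicks_t, clicks_sym, terminal_kind, terminal_t) {
  tibble::tibble(
    participant_id = pid, item_id = iid,
    t = c(clicks_t, terminal_t),
    kind = c(rep("click", length(clicks_t)), terminal_kind),
    symbol_id = c(clicks_sym, NA_character_)
  )
}

# direct synthesis of a crossed-design response with known incomplete-attempt
# effects, for mixed-model recovery checks
sim_iap_data <- function(n_p = 200, n_i = 22, b0 = 50, b_glob = 15, b_cur = 0,
                         sd_p = 5, sd_i = 3, sd_e = 8) {
  pid <- rep(sprintf("p%03d", seq_len(n_p)), each = n_i)
  iid <- rep(sprintf("i%02d", seq_len(n_i)), times = n_p)
  pi_iap <- rbeta(n_p, 0.5, 6)
  iap <- rbinom(n_p * n_i, 1, rep(pi_iap, each = n_i))
  g <- stats::ave(iap, pid)
  cur <- iap - g
  u <- rep(rnorm(n_p, 0, sd_p), each = n_i)
  v <- rep(rnorm(n_i, 0, sd_i), times = n_p)
  tibble::tibble(
    participant_id = pid, item_id = iid,
    iap_global = g, iap_current = cur,
    tot = b0 + b_glob * g + b_cur * cur + u + v + rnorm(n_p * n_i, 0, sd_e)
  )
}

# cache of default cohorts (and their feature tables), keyed by seed
cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(cohort_cache[[key]])) {
    co <- generate_cohort(seed = seed)
    feats <- participant_features(co$sessions, co$item_bank)
    cohort_cache[[key]] <- list(cohort = co, features = feats)
  }
  cohort_cache[[key]]
}
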