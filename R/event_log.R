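#' Read and validate an event log
#'
#' An event log records one timestamped event per row for a construction-based
#' matrix test session: clicks on construction-kit symbols plus one terminal
#' event (`submit` or `timeout`) per participant-item. Accepted on-disk
#' formats are CSV (header `participant_id,item_id,t,kind,symbol_id`) and
#' JSON-lines with the same keys; `t` is seconds from item onset with `.` as
#' decimal separator. Clicks act as select/deselect toggles: a repeated click
#' on a selected symbol deselects it.
#'
#' Validation enforces, per participant-item: nondecreasing `t`, `0 <= t <=
#' time_limit`, exactly one terminal event in last position, and symbols that
#' belong to the item's construction kit. Each click is annotated with the
#' rule its symbol group belongs to.
#'
#' @param path path to a `.csv` or `.jsonl`/`.ndjson` file.
#' @param item_bank an `lft_item_bank` resolving every `item_id`.
#' @return An `lft_sessions` tibble with columns `participant_id`, `item_id`,
#'   `t`, `kind`, `symbol_id`, `rule_id`, ordered by participant, item
#'   position and time; the item bank is attached as `attr(, "item_bank")`.
#' @export
read_event_log <- function(path, item_bank) {
  stopifnot(inherits(item_bank, "lft_item_bank"))
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
    df <- tibble::as_tibble(df)
    if (!"symbol_id" %in% names(df)) df$symbol_id <- NA_character_
  } else {
    df <- utils::read.csv(path, colClasses = c(
      participant_id = "character", item_id = "character", t = "numeric",
      kind = "character", symbol_id = "character"
    ))
    df <- tibble::as_tibble(df)
  }
  need <- c("participant_id", "item_id", "t", "kind", "symbol_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("event log lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- df[need]
  df$symbol_id[!is.na(df$symbol_id) & df$symbol_id == ""] <- NA_character_
  as_sessions(df, item_bank)
}

#' Build a validated session table from an in-memory event frame
#'
#' @param events data frame with columns `participant_id`, `item_id`, `t`,
#'   `kind`, `symbol_id`.
#' @param item_bank an `lft_item_bank`.
#' @return An `lft_sessions` tibble (see [read_event_log()]).
#' @export
as_sessions <- function(events, item_bank) {
  events <- tibble::as_tibble(events)
  unknown_item <- !(events$item_id %in% item_bank$item_id)
  if (any(unknown_item)) {
    abort(sprintf("row %d: unknown item_id `%s`",
                  which(unknown_item)[1], events$item_id[which(unknown_item)[1]]))
  }
  bad_kind <- !(events$kind %in% c("click", "submit", "timeout"))
  if (any(bad_kind)) {
    abort(sprintf("row %d: unknown event kind `%s`",
                  which(bad_kind)[1], events$kind[which(bad_kind)[1]]))
  }
  # annotate rule_id per click via the item's symbol-group map
  idx <- match(events$item_id, item_bank$item_id)
  events$rule_id <- NA_character_
  is_click <- events$kind == "click"
  if (any(is_click & is.na(events$symbol_id))) {
    abort(sprintf("row %d: click without symbol_id", which(is_click & is.na(events$symbol_id))[1]))
  }
  if (any(!is_click & !is.na(events$symbol_id))) {
    abort("terminal events must not carry a symbol_id")
  }
  for (i in which(is_click)) {
    lookup <- item_bank$symbol_rule[[idx[i]]]
    rid <- unname(lookup[events$symbol_id[i]])
    if (is.na(rid)) {
      abort(sprintf("row %d: symbol `%s` not in the construction kit of item `%s`",
                    i, events$symbol_id[i], events$item_id[i]))
    }
    events$rule_id[i] <- rid
  }
  # stable order: participant, then item position; the within-item event
  # order is the caller's and is validated, never repaired
  pos <- item_bank$position[idx]
  events <- events[order(events$participant_id, pos, method = "radix"), ,
                   drop = FALSE]
  validate_sessions(events, item_bank)
  attr(events, "item_bank") <- item_bank
  class(events) <- c("lft_sessions", setdiff(class(events), "lft_sessions"))
  events
}

#' Validate session invariants
#'
#' Per participant-item: `t` nondecreasing and within `[0, time_limit]`,
#' exactly one terminal (`submit`/`timeout`) event, and it is last.
#'
#' @param events event tibble (with `rule_id` column).
#' @param item_bank an `lft_item_bank`.
#' @return `events`, invisibly.
#' @export
validate_sessions <- function(events, item_bank) {
  limit <- setNames(item_bank$time_limit, item_bank$item_id)
  split_idx <- split(seq_len(nrow(events)),
                     list(events$participant_id, events$item_id), drop = TRUE)
  for (ix in split_idx) {
    pid <- events$participant_id[ix[1]]
    iid <- events$item_id[ix[1]]
    tt <- events$t[ix]
    kk <- events$kind[ix]
    where <- sprintf("participant `%s`, item `%s`", pid, iid)
    if (any(tt < 0) || any(tt > limit[[iid]])) {
      abort(sprintf("%s: event time outside [0, %g]", where, limit[[iid]]))
    }
    if (is.unsorted(tt)) abort(sprintf("%s: non-monotone event times", where))
    term <- kk %in% c("submit", "timeout")
    if (sum(term) != 1L) {
      abort(sprintf("%s: needs exactly one terminal event, found %d", where, sum(term)))
    }
    if (which(term) != length(kk)) {
      abort(sprintf("%s: events occur after the terminal event", where))
    }
  }
  invisible(events)
}

#' Write an event log to CSV
#'
#' Round-trip companion of [read_event_log()]: an empty session table yields
#' a header-only file, and `read_event_log(write_event_log(x, f), bank)`
#' equals `x`.
#'
#' @param sessions an `lft_sessions` tibble (or plain event frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sessions, path) {
  out <- as.data.frame(sessions)[c("participant_id", "item_id", "t", "kind", "symbol_id")]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(sprintf("cannot write event log to `%s`", path))
  invisible(path)
}

#' Replay click toggles into a final selection
#'
#' Clicks toggle symbols in and out of the constructed response: a symbol
#' clicked an odd number of times is selected, an even number of times
#' deselected.
#'
#' @param symbol_ids character vector of clicked symbol ids, in click order.
#' @return Character vector of selected symbol ids (first-click order).
#' @export
replay_selection <- function(symbol_ids) {
  counts <- table(factor(symbol_ids, levels = unique(symbol_ids)))
  names(counts)[as.integer(counts) %% 2L == 1L]
}

#' Per participant-item outcomes
#'
#' Replays every participant-item stream into its outcome: final selection,
#' correctness (selection equals the solution set exactly), terminal kind and
#' time-on-task (the terminal-event time).
#'
#' @param sessions an `lft_sessions` tibble.
#' @param item_bank an `lft_item_bank`; defaults to the one attached to
#'   `sessions`.
#' @return A tibble with one row per participant-item: `participant_id`,
#'   `item_id`, `position`, `n_rules`, `analysis`, `n_clicks`, `tot`,
#'   `terminal`, `correct`, and list-column `final_selection`.
#' @export
item_outcomes <- function(sessions, item_bank = attr(sessions, "item_bank")) {
  stopifnot(inherits(item_bank, "lft_item_bank"))
  solution <- setNames(item_bank$solution, item_bank$item_id)
  ev <- tibble::as_tibble(sessions)
  out <- ev |>
    dplyr::group_by(.data$participant_id, .data$item_id) |>
    dplyr::summarise(
      n_clicks = sum(.data$kind == "click"),
      tot = .data$t[.data$kind != "click"][1],
      terminal = .data$kind[.data$kind != "click"][1],
      final_selection = list(replay_selection(.data$symbol_id[.data$kind == "click"])),
      .groups = "drop"
    )
  out$correct <- purrr::map2_lgl(out$final_selection, out$item_id, function(sel, iid) {
    setequal(sel, solution[[iid]])
  })
  meta <- item_bank[c("item_id", "position", "n_rules", "analysis")]
  out <- dplyr::left_join(out, tibble::as_tibble(meta), by = "item_id")
  out <- out[order(out$participant_id, out$position), ]
  out[c("participant_id", "item_id", "position", "n_rules", "analysis",
        "n_clicks", "tot", "terminal", "correct", "final_selection")]
}
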