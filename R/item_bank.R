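#' Read an item bank from JSON
#'
#' An item bank describes the items of a construction-based matrix test: the
#' logical rules each item contains, the mapping from construction-kit symbol
#' groups to rules, the correct solution (a set of symbol ids) and the item
#' time limit. The JSON document has two top-level keys:
#'
#' * `symbol_groups`: an object mapping each group id to the character vector
#'   of symbol ids it contains;
#' * `items`: an array of objects with `item_id`, `position` (1-based order in
#'   the test), optional `time_limit` (seconds, default 90), `rules` (array of
#'   `{rule_id, symbol_group, n_required_clicks}`) and `solution` (array of
#'   symbol ids).
#'
#' Single-rule items load but are flagged `analysis = FALSE`: without at least
#' two rules an item carries no information about rule jumping or interrule
#' times, so the analysis set is restricted to multi-rule items.
#'
#' @param path path to the JSON file.
#' @return An `lft_item_bank`: a tibble with one row per item and columns
#'   `item_id`, `position`, `time_limit`, `n_rules`, `analysis`, plus
#'   list-columns `rules` (tibble of rule specs) and `solution` (character
#'   vector of symbol ids). The symbol-group table is kept in
#'   `attr(, "symbol_groups")` and a flat symbol-to-rule lookup per item in
#'   the `symbol_rule` list-column.
#' @seealso [default_item_bank()] for the packaged 22-item fixture bank,
#'   [write_item_bank()] for the inverse.
#' @export
read_item_bank <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("item bank is not valid JSON: %s", conditionMessage(e)))
  )
  if (is.null(doc$symbol_groups) || is.null(doc$items)) {
    abort("item bank JSON must contain `symbol_groups` and `items`")
  }
  groups <- lapply(doc$symbol_groups, function(g) vapply(g, as.character, character(1)))
  all_syms <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_syms)) {
    abort("symbol ids must be unique across symbol groups")
  }
  sym_group <- setNames(rep(names(groups), lengths(groups)), all_syms)

  items <- purrr::map(doc$items, function(it) {
    rules <- purrr::map_dfr(it$rules, function(r) {
      tibble::tibble(
        rule_id = as.character(r$rule_id),
        symbol_group = as.character(r$symbol_group),
        n_required_clicks = as.integer(r$n_required_clicks)
      )
    })
    tibble::tibble(
      item_id = as.character(it$item_id),
      position = as.integer(it$position),
      time_limit = as.numeric(it$time_limit %||% 90),
      rules = list(rules),
      solution = list(vapply(it$solution, as.character, character(1)))
    )
  })
  bank <- dplyr::bind_rows(items)
  bank$n_rules <- vapply(bank$rules, nrow, integer(1))
  bank$analysis <- bank$n_rules >= 2L
  bank$symbol_rule <- purrr::map(bank$rules, function(rules) {
    # symbol -> rule_id lookup for this item, via the group membership
    unlist(purrr::pmap(rules, function(rule_id, symbol_group, n_required_clicks) {
      g <- groups[[symbol_group]]
      if (is.null(g)) abort(sprintf("unknown symbol group `%s`", symbol_group))
      setNames(rep(rule_id, length(g)), g)
    }))
  })
  bank <- bank[order(bank$position), ]
  attr(bank, "symbol_groups") <- groups
  class(bank) <- c("lft_item_bank", class(bank))
  validate_item_bank(bank)
  bank
}

#' Validate an item bank
#'
#' Enforces the structural invariants of an item bank: positive time limits,
#' at least one rule per item, strictly increasing positions, rule symbol
#' groups that exist and are item-wise distinct, `n_required_clicks >= 1`,
#' and a solution in which every symbol maps to exactly one rule of the item
#' with exactly `n_required_clicks` solution symbols per rule.
#'
#' @param bank an `lft_item_bank`.
#' @return The bank, invisibly; errors describe the offending item.
#' @export
validate_item_bank <- function(bank) {
  if (!inherits(bank, "lft_item_bank")) abort("not an item bank")
  if (anyDuplicated(bank$item_id)) abort("duplicated item_id in item bank")
  if (any(diff(sort(bank$position)) == 0L)) abort("item positions must be strictly increasing")
  for (i in seq_len(nrow(bank))) {
    id <- bank$item_id[i]
    rules <- bank$rules[[i]]
    if (nrow(rules) < 1L) abort(sprintf("item `%s` has no rules", id))
    if (bank$time_limit[i] <= 0) abort(sprintf("item `%s` has non-positive time limit", id))
    if (any(rules$n_required_clicks < 1L)) {
      abort(sprintf("item `%s` has a rule with n_required_clicks < 1", id))
    }
    if (anyDuplicated(rules$symbol_group)) {
      abort(sprintf("item `%s` assigns two rules to the same symbol group", id))
    }
    lookup <- bank$symbol_rule[[i]]
    sol <- bank$solution[[i]]
    unknown <- setdiff(sol, names(lookup))
    if (length(unknown)) {
      abort(sprintf("item `%s`: solution symbol(s) %s not in any rule's symbol group",
                    id, paste(unknown, collapse = ", ")))
    }
    per_rule <- table(factor(lookup[sol], levels = rules$rule_id))
    if (!all(as.integer(per_rule) == rules$n_required_clicks)) {
      abort(sprintf("item `%s`: solution symbols per rule do not match n_required_clicks", id))
    }
  }
  invisible(bank)
}

#' Write an item bank to JSON
#'
#' Inverse of [read_item_bank()]; `read_item_bank(write_item_bank(bank, f))`
#' reproduces the bank.
#'
#' @param bank an `lft_item_bank`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  validate_item_bank(bank)
  doc <- list(
    symbol_groups = attr(bank, "symbol_groups"),
    items = purrr::pmap(
      list(bank$item_id, bank$position, bank$time_limit, bank$rules, bank$solution),
      function(item_id, position, time_limit, rules, solution) {
        list(
          item_id = item_id, position = position, time_limit = time_limit,
          rules = purrr::pmap(rules, function(rule_id, symbol_group, n_required_clicks) {
            list(rule_id = rule_id, symbol_group = symbol_group,
                 n_required_clicks = n_required_clicks)
          }),
          solution = as.list(solution)
        )
      }
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The packaged 22-item fixture bank
#'
#' A fixture item bank mirroring the composition of the analysed multi-rule
#' item set of a published construction-based matrix test: 22 items with
#' eleven two-rule, seven three-rule, three four-rule and one five-rule item,
#' six symbol groups of four symbols each, seven rule types, and a 90-second
#' item time limit. Symbol assignments and solutions are synthetic (the
#' original stimuli are copyrighted); only the structural composition is
#' mirrored.
#'
#' @return An `lft_item_bank` with 22 items.
#' @export
default_item_bank <- function() {
  read_item_bank(system.file("extdata", "item_bank.json", package = "lftimes",
                             mustWork = TRUE))
}

#' @export
print.lft_item_bank <- function(x, ...) {
  cat(sprintf("<lft_item_bank> %d items (%d in analysis set), rule counts: %s\n",
              nrow(x), sum(x$analysis),
              paste(sprintf("%d-rule: %d", as.integer(names(table(x$n_rules))),
                            as.integer(table(x$n_rules))), collapse = ", ")))
  NextMethod()
}
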