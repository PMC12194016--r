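#' Crossed random-intercept model for incomplete-attempt effects
#'
#' Predicts a per participant-item response time (ToT or the item-level
#' interrule time) from the participant's global incomplete-attempt
#' propensity and the group-mean-centred current indicator, controlling for
#' participant and item effects through crossed random intercepts:
#'
#' `time ~ iap_global + iap_current + (1 | participant) + (1 | item)`
#'
#' Estimated by REML via `lme4`, with Satterthwaite p-values from
#' `lmerTest`.
#'
#' @param data long tibble with one row per participant-item.
#' @param response name of the response column (e.g. `"tot"` or `"inter"`).
#' @param iap_global,iap_current,participant,item column names (defaults
#'   match [participant_features()] output).
#' @return A list of class `lft_mixed`: `fixed` (tibble of estimate, se, df,
#'   t, p per fixed effect), `variance_components` (participant, item,
#'   residual), and the fitted `model`.
#' @export
iap_mixed_model <- function(data, response = "tot",
                            iap_global = "iap_global", iap_current = "iap_current",
                            participant = "participant_id", item = "item_id") {
  need <- c(response, iap_global, iap_current, participant, item)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("data lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- data.frame(
    y = data[[response]],
    g = data[[iap_global]], c = data[[iap_current]],
    pid = factor(data[[participant]]), iid = factor(data[[item]])
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- tryCatch(
    lmerTest::lmer(y ~ g + c + (1 | pid) + (1 | iid), data = df, REML = TRUE),
    error = function(e) abort(sprintf("mixed model failed: %s", conditionMessage(e)))
  )
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$messages) && any(grepl("failed to converge", conv$messages))) {
    abort(sprintf("mixed model did not converge: %s",
                  paste(conv$messages, collapse = "; ")))
  }
  sm <- summary(fit)$coefficients
  rn <- c("(Intercept)", "g", "c")
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- setNames(vc$vcov, vc$grp)
  structure(list(
    fixed = tibble::tibble(
      term = c("intercept", "iap_global", "iap_current"),
      estimate = sm[rn, "Estimate"],
      se = sm[rn, "Std. Error"],
      df = sm[rn, "df"],
      t = sm[rn, "t value"],
      p = sm[rn, "Pr(>|t|)"]
    ),
    variance_components = tibble::tibble(
      component = c("participant", "item", "residual"),
      variance = unname(c(vcomp[["pid"]], vcomp[["iid"]], vcomp[["Residual"]]))
    ),
    model = fit
  ), class = "lft_mixed")
}

#' @export
print.lft_mixed <- function(x, ...) {
  cat("<lft_mixed> crossed random-intercept model\n")
  print(x$fixed)
  print(x$variance_components)
  invisible(x)
}
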