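#' Quadratic time-on-task effect
#'
#' Tests the inverted-U relation between test performance and mean time on
#' task by fitting `score ~ z(ToT) + z(ToT)^2` and comparing it with the
#' linear model `score ~ z(ToT)`. Reports the standardized quadratic beta
#' (`b * sd(predictor) / sd(score)`), the R-squared of the quadratic model,
#' the increment over the linear model and the F-change test on
#' `(1, n - 3)` degrees of freedom.
#'
#' @param score,tot numeric vectors (complete cases used, n >= 10).
#' @return A tibble with `beta_quadratic`, `beta_linear`, `r2_quadratic`,
#'   `r2_linear`, `delta_r2`, `f_change`, `df1`, `df2`, `p`.
#' @export
quadratic_tot_effect <- function(score, tot) {
  ok <- is.finite(score) & is.finite(tot)
  score <- score[ok]; tot <- tot[ok]
  n <- length(score)
  if (n < 10) abort("quadratic time-on-task test needs n >= 10")
  if (stats::sd(tot) == 0 || stats::sd(score) == 0) abort("degenerate variance")
  z <- as.numeric(scale(tot))
  z2 <- z^2
  m_lin <- stats::lm(score ~ z)
  m_quad <- stats::lm(score ~ z + z2)
  r2l <- summary(m_lin)$r.squared
  r2q <- summary(m_quad)$r.squared
  f <- (r2q - r2l) / ((1 - r2q) / (n - 3))
  tibble::tibble(
    beta_quadratic = unname(stats::coef(m_quad)["z2"]) * stats::sd(z2) / stats::sd(score),
    beta_linear = unname(stats::coef(m_quad)["z"]) / stats::sd(score),
    r2_quadratic = r2q, r2_linear = r2l, delta_r2 = r2q - r2l,
    f_change = f, df1 = 1L, df2 = n - 3L,
    p = stats::pf(f, 1, n - 3, lower.tail = FALSE)
  )
}

#' Hierarchical regression of performance on ToT and the log-file times
#'
#' Model 1 regresses the test score on the mean time on task alone; model 2
#' adds the three log-file times (onset, interrule, intrarule). Reports
#' standardized betas, each predictor's unique R-squared (squared
#' semipartial: the drop in model R-squared when that predictor is removed),
#' the R-squared increment of model 2 with its F-change test on
#' `(3, n - 5)` degrees of freedom, and variance inflation factors of
#' model 2.
#'
#' @param score,tot,onset,inter,intra numeric vectors; complete cases used.
#' @return A list of class `lft_hierarchical`: `coefficients` (per-predictor
#'   tibble with `beta`, `t`, `p`, `unique_r2`, `vif`), `models` (R-squared
#'   and overall F of both models), `delta_r2`, `f_change`, `df1`, `df2`,
#'   `p_change`, `n`.
#' @export
hierarchical_regression <- function(score, tot, onset, inter, intra) {
  dat <- data.frame(score = score, tot = tot, onset = onset,
                    inter = inter, intra = intra)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= 10) abort("hierarchical regression needs n > 10")
  preds <- c("tot", "onset", "inter", "intra")
  sds <- vapply(dat, stats::sd, numeric(1))
  if (any(sds == 0)) abort(sprintf("constant column: %s", names(sds)[sds == 0][1]))

  m1 <- stats::lm(score ~ tot, data = dat)
  m2 <- stats::lm(score ~ tot + onset + inter + intra, data = dat)
  if (any(is.na(stats::coef(m2)))) {
    bad <- names(stats::coef(m2))[is.na(stats::coef(m2))][1]
    abort(sprintf("perfect collinearity involving predictor `%s`", bad))
  }
  r2_1 <- summary(m1)$r.squared
  r2_2 <- summary(m2)$r.squared

  # unique R^2: drop in R^2 when the predictor is removed from model 2
  unique_r2 <- vapply(preds, function(p) {
    mr <- stats::lm(stats::as.formula(paste("score ~", paste(setdiff(preds, p), collapse = " + "))),
                    data = dat)
    r2_2 - summary(mr)$r.squared
  }, numeric(1))

  # VIF = 1 / (1 - R^2 of predictor on the other predictors)
  vif <- vapply(preds, function(p) {
    mp <- stats::lm(stats::as.formula(paste(p, "~", paste(setdiff(preds, p), collapse = " + "))),
                    data = dat)
    r2p <- summary(mp)$r.squared
    if (r2p >= 1 - 1e-12) abort(sprintf("perfect collinearity involving predictor `%s`", p))
    1 / (1 - r2p)
  }, numeric(1))

  sm2 <- summary(m2)$coefficients
  beta <- stats::coef(m2)[preds] * sds[preds] / sds["score"]
  f_change <- ((r2_2 - r2_1) / 3) / ((1 - r2_2) / (n - 5))
  structure(list(
    coefficients = tibble::tibble(
      predictor = preds,
      beta = unname(beta),
      t = sm2[preds, "t value"],
      p = sm2[preds, "Pr(>|t|)"],
      unique_r2 = unname(unique_r2),
      vif = unname(vif)
    ),
    models = tibble::tibble(
      model = c("tot_only", "tot_and_lft"),
      r2 = c(r2_1, r2_2),
      f = c(summary(m1)$fstatistic[1], summary(m2)$fstatistic[1]),
      df1 = c(1L, 4L), df2 = c(n - 2L, n - 5L)
    ),
    delta_r2 = r2_2 - r2_1, f_change = f_change,
    df1 = 3L, df2 = n - 5L,
    p_change = stats::pf(f_change, 3, n - 5, lower.tail = FALSE),
    n = n
  ), class = "lft_hierarchical")
}

#' @export
print.lft_hierarchical <- function(x, ...) {
  cat(sprintf("<lft_hierarchical> n = %d, R2 %.1f%% -> %.1f%% (delta %.1f%%, F(%d, %d) = %.2f, p = %.3g)\n",
              x$n, 100 * x$models$r2[1], 100 * x$models$r2[2], 100 * x$delta_r2,
              x$df1, x$df2, x$f_change, x$p_change))
  print(x$coefficients)
  invisible(x)
}

#' Incremental variance of an added predictor
#'
#' Nested OLS comparison: does `addition` explain score variance beyond
#' `covariate`? Reports both R-squared values, the increment and the
#' F-change on `(1, n - 3)` degrees of freedom — the form used for
#' external/incremental validation against a second test score.
#'
#' @param score,covariate,addition numeric vectors; complete cases used.
#' @return A tibble with `r2_base`, `r2_full`, `delta_r2`, `f`, `df1`,
#'   `df2`, `p`.
#' @export
incremental_r2 <- function(score, covariate, addition) {
  dat <- data.frame(score = score, covariate = covariate, addition = addition)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 5) abort("too few complete cases")
  m0 <- stats::lm(score ~ covariate, data = dat)
  m1 <- stats::lm(score ~ covariate + addition, data = dat)
  r2_0 <- summary(m0)$r.squared
  r2_1 <- summary(m1)$r.squared
  if (is.na(stats::coef(m1)["addition"])) {
    # addition is collinear with the covariate: no increment by definition
    r2_1 <- r2_0
  }
  f <- (r2_1 - r2_0) / ((1 - r2_1) / (n - 3))
  tibble::tibble(r2_base = r2_0, r2_full = r2_1, delta_r2 = r2_1 - r2_0,
                 f = f, df1 = 1L, df2 = n - 3L,
                 p = stats::pf(f, 1, n - 3, lower.tail = FALSE))
}
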