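#' Parallel mediation path model for the interrule-performance relation
#'
#' Fits the recursive four-variable path model in which the effect of the
#' interrule times (X) on the test score (Y) is carried in parallel by the
#' intrarule times (M1) and the rule-jump score (M2):
#'
#' ```
#'   M1 = a1 X + e1
#'   M2 = a2 X + e2
#'   Y  = c' X + b1 M1 + b2 M2 + eY
#' ```
#'
#' All variables are z-standardized, so the path coefficients are
#' standardized betas estimated by the model's ordinary least squares
#' regressions. The indirect effects are `a1*b1` and `a2*b2`, and the total
#' effect is `direct + indirect1 + indirect2` (an algebraic identity of the
#' estimates). The covariance of the mediator residuals is fixed to zero,
#' which leaves one overidentified moment and hence one model degree of
#' freedom; `free_mediator_cov = TRUE` frees it, giving the saturated
#' (just-identified) model with zero discrepancy.
#'
#' Fit indices come from the maximum-likelihood discrepancy between the
#' sample covariance `S` and the model-implied covariance `Sigma`:
#' `F_ML = log det Sigma - log det S + tr(S Sigma^-1) - p`, with
#' `chi^2 = (n-1) F_ML` (the conventional SEM scaling), `RMSEA =
#' sqrt(max(chi^2 - df, 0) / (df (n-1)))`, CFI against the independence
#' baseline, and SRMR as the root mean square of the standardized residual
#' covariances.
#'
#' Confidence intervals are percentile bootstrap over `B` resamples of
#' participants; point estimates do not depend on the bootstrap seed.
#'
#' @param inter,intra,jumps,score numeric vectors (complete cases required,
#'   n >= 30).
#' @param B bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap resampling.
#' @param conf confidence level (default 0.95).
#' @param free_mediator_cov free the mediator residual covariance
#'   (saturated model, df = 0).
#' @return A list of class `lft_mediation`: `paths` (tibble of a1, a2, b1,
#'   b2, direct, indirect1, indirect2, total with bootstrap CIs), `fit`
#'   (chisq, df, p, cfi, rmsea, srmr, n), `r_squared` for the three
#'   regressions, `B`, `seed`.
#' @export
mediation_path <- function(inter, intra, jumps, score, B = 1000, seed = NULL,
                           conf = 0.95, free_mediator_cov = FALSE) {
  dat <- cbind(X = inter, M1 = intra, M2 = jumps, Y = score)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 30) abort("mediation model needs at least 30 complete cases")
  if (any(apply(dat, 2, stats::sd) == 0)) abort("constant variable in mediation model")
  S <- stats::cov(dat)
  if (abs(det(S)) < 1e-12) abort("singular covariance in mediation model")
  R <- stats::cov2cor(S)

  est <- path_estimates(R)
  fit <- path_fit(R, est, n, free_mediator_cov)

  boot_ci <- NULL
  if (B > 0) {
    run_boot <- function() {
      draws <- matrix(NA_real_, nrow = B, ncol = 8)
      for (b in seq_len(B)) {
        ix <- sample.int(n, n, replace = TRUE)
        Sb <- stats::cov(dat[ix, , drop = FALSE])
        if (any(diag(Sb) == 0)) next
        eb <- path_estimates(stats::cov2cor(Sb))
        draws[b, ] <- unlist(eb)
      }
      draws
    }
    draws <- if (is.null(seed)) run_boot() else withr::with_seed(as.integer(seed), run_boot())
    a <- (1 - conf) / 2
    boot_ci <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  }

  paths <- tibble::tibble(
    path = c("a1", "a2", "b1", "b2", "direct", "indirect1", "indirect2", "total"),
    label = c("inter -> intra", "inter -> jumps", "intra -> score",
              "jumps -> score", "inter -> score (direct)",
              "via intra", "via jumps", "total"),
    estimate = unlist(est)
  )
  if (!is.null(boot_ci)) {
    paths$ci_lower <- boot_ci[1, ]
    paths$ci_upper <- boot_ci[2, ]
  }
  structure(list(paths = paths, fit = fit,
                 r_squared = attr(est, "r_squared"), B = B, seed = seed, n = n),
            class = "lft_mediation")
}

# Closed-form path estimates from the correlation matrix (equivalent to the
# OLS regressions on standardized variables).
path_estimates <- function(R) {
  a1 <- R["X", "M1"]
  a2 <- R["X", "M2"]
  pred <- c("X", "M1", "M2")
  beta <- solve(R[pred, pred], R[pred, "Y"])
  direct <- beta[["X"]]; b1 <- beta[["M1"]]; b2 <- beta[["M2"]]
  out <- list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, direct = direct,
              indirect1 = a1 * b1, indirect2 = a2 * b2,
              total = direct + a1 * b1 + a2 * b2)
  attr(out, "r_squared") <- c(
    intra = a1^2, jumps = a2^2,
    score = sum(beta * R[pred, "Y"])
  )
  out
}

# Model-implied covariance and ML fit indices.
path_fit <- function(R, est, n, free_mediator_cov) {
  p <- 4L
  a1 <- est$a1; a2 <- est$a2; b1 <- est$b1; b2 <- est$b2; cp <- est$direct
  r_m1m2 <- if (free_mediator_cov) R["M1", "M2"] else a1 * a2
  sigma <- diag(1, p)
  dimnames(sigma) <- dimnames(R)
  sigma["X", "M1"] <- sigma["M1", "X"] <- a1
  sigma["X", "M2"] <- sigma["M2", "X"] <- a2
  sigma["M1", "M2"] <- sigma["M2", "M1"] <- r_m1m2
  sigma["X", "Y"] <- sigma["Y", "X"] <- cp + b1 * a1 + b2 * a2
  sigma["M1", "Y"] <- sigma["Y", "M1"] <- cp * a1 + b1 + b2 * r_m1m2
  sigma["M2", "Y"] <- sigma["Y", "M2"] <- cp * a2 + b1 * r_m1m2 + b2
  # residual variance of Y reproduces the sample variance of Y under the
  # fitted regression, so the implied variance stays 1 up to the constrained
  # mediator covariance entering the explained part
  beta <- c(cp, b1, b2)
  pred <- c("X", "M1", "M2")
  psi_y <- 1 - sum(beta * R[pred, "Y"])
  sigma["Y", "Y"] <- drop(beta %*% sigma[pred, pred] %*% beta) + psi_y

  df <- if (free_mediator_cov) 0L else 1L
  f_ml <- as.numeric(determinant(sigma)$modulus - determinant(R)$modulus +
                       sum(diag(R %*% solve(sigma))) - p)
  f_ml <- max(f_ml, 0)
  chisq <- (n - 1) * f_ml
  chisq_base <- -(n - 1) * as.numeric(determinant(R)$modulus)
  df_base <- p * (p - 1) / 2
  cfi <- if (df == 0L) 1 else {
    denom <- max(chisq_base - df_base, chisq - df, 0)
    if (denom == 0) 1 else 1 - max(chisq - df, 0) / denom
  }
  rmsea <- if (df == 0L) 0 else sqrt(max(chisq - df, 0) / (df * (n - 1)))
  resid <- R - sigma
  srmr <- sqrt(mean(resid[lower.tri(resid, diag = TRUE)]^2))
  list(chisq = chisq, df = df,
       p = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
       cfi = cfi, rmsea = rmsea, srmr = srmr, n = n)
}

#' @export
print.lft_mediation <- function(x, ...) {
  cat(sprintf("<lft_mediation> n = %d, chisq(%d) = %.2f, CFI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$n, x$fit$df, x$fit$chisq, x$fit$cfi, x$fit$rmsea, x$fit$srmr))
  print(x$paths)
  invisible(x)
}
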