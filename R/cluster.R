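#' Hierarchical strategy clustering with silhouette-based model selection
#'
#' Clusters participants by hierarchical agglomerative clustering (Ward's
#' method on Euclidean distances, `ward.D2` convention: the merge cost is the
#' increase in total within-cluster sum of squares, heights on the original
#' distance scale). Columns are z-standardized internally. The number of
#' clusters is chosen by the maximum average silhouette width over
#' `k_range` intersected with `[2, 10]`; `k = 1` is admitted only when every
#' candidate solution has an average silhouette below `weak_threshold`
#' (weak-structure flag). Stability is assessed by `B` bootstrap resamples of
#' participants: each resample is reclustered at the selected `k` and the
#' average silhouette and the pairwise co-assignment agreement with the
#' original labels are recorded.
#'
#' @param features numeric matrix or data frame (participants x variables,
#'   typically test score and interrule time).
#' @param k_range candidate cluster counts (default `1:10`).
#' @param B bootstrap resamples (default 100).
#' @param seed optional seed for the bootstrap.
#' @param weak_threshold silhouette below which structure counts as weak
#'   (default 0.25).
#' @return A list of class `lft_clusters`: `k`, `labels`, `silhouette`
#'   (average width of the selected solution), `silhouette_by_k`, `hclust`
#'   (the fitted tree), `weak_structure`, and `bootstrap` (tibble of
#'   per-resample average silhouette and co-assignment agreement).
#' @export
ward_cluster <- function(features, k_range = 1:10, B = 100, seed = NULL,
                         weak_threshold = 0.25) {
  x <- as.matrix(features)
  if (!all(is.finite(x))) abort("features must be finite")
  n <- nrow(x)
  if (n < max(k_range)) abort("more candidate clusters than observations")
  xs <- scale(x)
  if (any(!is.finite(xs))) abort("a feature column is constant; clustering is degenerate")
  d <- stats::dist(xs)
  if (all(d == 0)) abort("all points identical; clustering is degenerate")
  hc <- stats::hclust(d, method = "ward.D2")

  ks <- sort(intersect(k_range, 2:10))
  if (!length(ks)) abort("k_range must contain a value in 2..10")
  sil_by_k <- vapply(ks, function(k) {
    mean(cluster::silhouette(stats::cutree(hc, k), d)[, "sil_width"])
  }, numeric(1))
  if (all(sil_by_k < weak_threshold) && 1 %in% k_range) {
    k_sel <- 1L
    labels <- rep(1L, n)
    sil <- NA_real_
    weak <- TRUE
  } else {
    k_sel <- ks[which.max(sil_by_k)]
    labels <- stats::cutree(hc, k_sel)
    sil <- max(sil_by_k)
    weak <- FALSE
  }

  boot <- NULL
  if (B > 0 && k_sel > 1L) {
    run_boot <- function() {
      purrr::map_dfr(seq_len(B), function(b) {
        ix <- sample.int(n, n, replace = TRUE)
        ux <- unique(ix)
        db <- stats::dist(xs[ix, , drop = FALSE])
        hb <- stats::hclust(db, method = "ward.D2")
        lb <- stats::cutree(hb, k_sel)
        sb <- mean(cluster::silhouette(lb, db)[, "sil_width"])
        # co-assignment agreement on the unique resampled points
        lb_u <- lb[match(ux, ix)]
        lo_u <- labels[ux]
        agree <- if (length(ux) > 1) {
          pairs_b <- outer(lb_u, lb_u, "==")
          pairs_o <- outer(lo_u, lo_u, "==")
          ut <- upper.tri(pairs_b)
          mean(pairs_b[ut] == pairs_o[ut])
        } else NA_real_
        tibble::tibble(silhouette = sb, agreement = agree)
      })
    }
    boot <- if (is.null(seed)) run_boot() else withr::with_seed(as.integer(seed), run_boot())
  }

  structure(list(k = k_sel, labels = unname(labels), silhouette = sil,
                 silhouette_by_k = tibble::tibble(k = ks, silhouette = sil_by_k),
                 hclust = hc, weak_structure = weak, bootstrap = boot,
                 scaled = xs),
            class = "lft_clusters")
}

#' @export
print.lft_clusters <- function(x, ...) {
  cat(sprintf("<lft_clusters> k = %d (avg silhouette %.2f%s), sizes: %s\n",
              x$k, x$silhouette,
              if (x$weak_structure) ", weak structure" else "",
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Welch two-sample comparison with Cohen's d
#'
#' Welch's t statistic with Welch-Satterthwaite degrees of freedom, paired
#' with a pooled-SD Cohen's d (`(mean(x2) - mean(x1)) / pooled SD`), the
#' combination conventionally reported for cluster contrasts.
#'
#' @param x1,x2 numeric vectors (the two groups).
#' @return A tibble with `t`, `df`, `p`, `d`, `m1`, `m2`.
#' @export
compare_clusters <- function(x1, x2) {
  x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
  if (length(x1) < 2 || length(x2) < 2) abort("both groups need at least 2 values")
  if (stats::var(x1) == 0 && stats::var(x2) == 0) abort("zero variance in both groups")
  tt <- stats::t.test(x2, x1, var.equal = FALSE)
  n1 <- length(x1); n2 <- length(x2)
  sp <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2))
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    d = (mean(x2) - mean(x1)) / sp, m1 = mean(x1), m2 = mean(x2)
  )
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors (n >= 4), complete cases used.
#' @param conf confidence level (default 0.95).
#' @return A tibble with `r`, `ci_lower`, `ci_upper`, `p`, `n`.
#' @export
correlation_ci <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4) abort("need at least 4 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) abort("constant input")
  ct <- stats::cor.test(x[ok], y[ok], conf.level = conf)
  tibble::tibble(r = unname(ct$estimate),
                 ci_lower = ct$conf.int[1], ci_upper = ct$conf.int[2],
                 p = ct$p.value, n = sum(ok))
}
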