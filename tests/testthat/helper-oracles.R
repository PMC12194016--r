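# Independent brute-force oracles, kept deliberately naive.

# O(n^3) Ward agglomeration from the centroid formula: the merge cost of
# clusters A, B is sqrt(2 |A||B| / (|A|+|B|)) * ||centroid_A - centroid_B||.
ward_oracle <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE])
        cb <- colMeans(x[b, , drop = FALSE])
        cost <- sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
          sqrt(sum((ca - cb)^2))
        if (cost < best[1]) best <- c(cost, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# silhouette widths straight from the definition
silhouette_oracle <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# covariance-form Cronbach alpha
alpha_oracle <- function(mat) {
  C <- stats::cov(mat)
  k <- ncol(mat)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# closed-form path coefficients from a correlation matrix, written out
# longhand (normal equations) rather than via the package's solver
paths_oracle <- function(R) {
  a1 <- R[1, 2]; a2 <- R[1, 3]
  rxy <- R[1, 4]; rm1y <- R[2, 4]; rm2y <- R[3, 4]
  P <- R[1:3, 1:3]
  beta <- solve(P) %*% c(rxy, rm1y, rm2y)
  list(a1 = a1, a2 = a2, direct = beta[1], b1 = beta[2], b2 = beta[3])
}
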