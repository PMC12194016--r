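# Internal helpers shared across modules.

# z-standardize a numeric vector; errors on zero variance unless allow_const.
zstd <- function(x, allow_const = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_const) return(rep(0, length(x)))
    abort("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Draw a derived RNG substream seed from a root seed; stays inside 32-bit range.
substream_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% .Machine$integer.max
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same points;
#' 1 means identical partitions (up to label permutation), 0 is the expected
#' agreement of independent labelings.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A single number in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
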