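#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used throughout the test suite to compare recovered clusters with the
#' planted ground truth; 1 means identical partitions up to label
#' permutation, 0 is the expectation under independent random labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Per-row variance of a dense matrix without forming apply() closures per row.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(0, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Nearest-rank order statistic: the k-th smallest value where k = rank.
nearest_rank <- function(x, rank) {
  stopifnot(rank >= 1, rank <= length(x))
  sort(x, partial = rank)[rank]
}

# Draw one sub-seed per consumer from a master seed, keeping values in the
# 32-bit signed integer range expected by set.seed().
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
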