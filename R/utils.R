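#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two hard partitions of the same
#' subjects. 1 means the partitions are identical up to relabeling; 0 is the
#' expected value under independent random partitions.
#'
#' @param a,b vectors of class labels (any atomic type), same length, aligned
#'   element-by-element.
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have the same length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Largest-remainder allocation of n units to proportions
#'
#' Deterministic apportionment: floors of n * p, then the remaining units go
#' to the classes with the largest fractional remainders (ties broken by
#' class order). Guarantees the counts sum to n exactly.
#'
#' @param n total count.
#' @param proportions non-negative weights summing to 1.
#' @return integer vector of counts, same length as `proportions`.
#' @export
largest_remainder <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- raw - counts
    top <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(short)]
    counts[top] <- counts[top] + 1L
  }
  as.integer(counts)
}

# near-equal contiguous split sizes: larger groups first
split_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  as.integer(rep(base, k) + c(rep(1L, rem), rep(0L, k - rem)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
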