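# Small numeric helpers shared across modules.

#' Geometric mean
#'
#' @param x numeric vector, strictly positive where observed.
#' @param na.rm drop missing values first.
#' @return the geometric mean, or `NA` if nothing is observed.
#' @keywords internal
geo_mean <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# Deterministic sub-seed for a named RNG stream, kept below 2^31 so it is a
# valid R integer seed.  One stream per logical component of the simulator
# means toggling e.g. missingness does not perturb the quantitative draws.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 65011 + 1) * 32749 + stream * 7919) %% 2147483647L
}

#' Adjusted Rand index between two partitions
#'
#' Used to quantify how well unsupervised clustering of a normalized matrix
#' recovers known sample groups.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return the adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
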