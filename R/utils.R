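#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without underflow.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Percent divergence between two aligned sequences
#'
#' Counts mismatching positions between two equal-length character strings
#' (e.g. two mitochondrial COI haplotypes) and expresses them as a
#' percentage of the alignment length.
#'
#' @param a,b character scalars of equal nchar (aligned sequences).
#' @return percent divergence (0-100).
#' @export
#' @examples
#' a <- strrep("A", 10)
#' b <- paste0(strrep("A", 9), "G")
#' percent_sequence_divergence(a, b) # 10
percent_sequence_divergence <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  100 * sum(av != bv) / length(av)
}

#' Whittaker multiplicative beta diversity
#'
#' @param gamma total (regional) richness.
#' @param alpha mean per-site richness.
#' @return beta = gamma / alpha.
#' @export
whittaker_beta <- function(gamma, alpha) {
  stopifnot(alpha > 0)
  gamma / alpha
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two labelings of the same individuals, corrected for
#' chance; 1 means identical partitions.
#'
#' @param x,y label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  n <- comb2(length(x))
  expected <- a * b / n
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Combine independent p-values with Fisher's method
#'
#' @param p vector of p-values (NA dropped).
#' @return combined p-value from the chi-squared distribution with 2k df.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Progressive Holm correction for correlogram p-values
#'
#' The k-th distance class is corrected as if only the first k classes had
#' been tested (the usual correlogram convention, reading classes from the
#' shortest distance outward).
#'
#' @param p raw p-values ordered by increasing distance class.
#' @param progressive if `FALSE`, ordinary simultaneous Holm across all
#'   classes.
#' @return corrected p-values.
#' @export
holm_progressive <- function(p, progressive = TRUE) {
  if (!progressive) return(stats::p.adjust(p, method = "holm"))
  vapply(seq_along(p), function(k) {
    if (is.na(p[k])) return(NA_real_)
    stats::p.adjust(p[seq_len(k)], method = "holm")[k]
  }, numeric(1))
}

# deterministic modal value; ties broken toward the smallest value
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])  # which.max takes first => lowest
}

# derive a bounded child seed from a root seed and a stage offset
child_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483629L
}
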