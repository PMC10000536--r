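# Gray-level histogram construction and the Kapur-entropy objective.
#
# Conventions frozen here and used everywhere else:
#   * histograms always have 256 bins (gray levels 0..255), whatever the
#     observed dynamic range;
#   * a threshold belongs to the LOWER class: classes are [0..t1],
#     [t1+1..t2], ..., [tk+1..255]; duplicated thresholds yield empty
#     classes with zero entropy;
#   * natural logarithm; 0*ln 0 := 0.

NLEV <- 256L

# round half away from zero upward: 0.5 -> 1, 5.5 -> 6 (base round() banks)
roundHalfUp <- function(x) floor(x + 0.5)

assertGrayImage <- function(image) {
  if (!is.matrix(image) || length(image) == 0)
    stop("empty input: image must be a non-empty matrix")
  if (any(is.na(image)) || any(image < 0) || any(image > 255) ||
      any(image != floor(image)))
    stop("image must contain integer intensities in [0, 255]")
  invisible(TRUE)
}

assertHistogram <- function(p) {
  if (length(p) != NLEV || any(is.na(p)) || any(p < 0))
    stop("histogram must be 256 non-negative probabilities")
  if (abs(sum(p) - 1) > 1e-8)
    stop("histogram must sum to 1")
  invisible(TRUE)
}

assertThresholds <- function(thresholds) {
  t <- thresholds
  if (length(t) && (any(is.na(t)) || any(t < 0) || any(t > 255) ||
                    any(t != floor(t))))
    stop("thresholds must be integers in [0, 255]")
  if (is.unsorted(t)) stop("thresholds must be sorted non-decreasing")
  invisible(TRUE)
}

#' Normalized 256-bin gray-level histogram of an image
#'
#' @param image integer matrix with values in \[0, 255\].
#' @return numeric vector of length 256; entry j+1 is the fraction of pixels
#'   equal to gray level j. Sums to 1.
#' @examples
#' h <- computeHistogram(matrix(c(0, 0, 255, 255), 2, 2))
#' h[1]    # 0.5
#' @export
computeHistogram <- function(image) {
  assertGrayImage(image)
  tabulate(as.integer(image) + 1L, nbins = NLEV) / length(image)
}

#' Gray-level class partition induced by a threshold set
#'
#' Class 0 covers `[0..t1]`, class i covers `[t_i + 1 .. t_{i+1}]`, and the
#' last class covers `[t_k + 1 .. 255]`. Duplicated thresholds produce empty
#' classes (`lo > hi`).
#'
#' @param thresholds sorted integer vector in \[0, 255\] (possibly empty).
#' @return data.frame with columns `lo`, `hi` (inclusive gray-level bounds),
#'   one row per class (k + 1 rows).
#' @export
partitionClasses <- function(thresholds) {
  assertThresholds(thresholds)
  t <- as.integer(thresholds)
  lo <- c(0L, t + 1L)
  hi <- c(t, 255L)
  data.frame(lo = lo, hi = hi)
}

# Zero-padded prefix sums that make each class entropy O(1):
#   cp0[j+2] = sum_{l<=j} p_l,   cplp0[j+2] = sum_{l<=j} p_l * ln p_l
kapurCumsums <- function(p) {
  plp <- numeric(NLEV)
  pos <- p > 0
  plp[pos] <- p[pos] * log(p[pos])
  list(cp0 = c(0, cumsum(p)), cplp0 = c(0, cumsum(plp)))
}

# fitness from prefix sums; thresholds already valid integers sorted
kapurEval <- function(cs, thresholds) {
  lo <- c(0L, thresholds + 1L)
  hi <- c(thresholds, 255L)
  keep <- lo <= hi
  lo <- lo[keep]; hi <- hi[keep]
  A <- cs$cp0[hi + 2L] - cs$cp0[lo + 1L]
  S <- cs$cplp0[hi + 2L] - cs$cplp0[lo + 1L]
  pos <- A > 0
  # H_i = -(1/A) sum p ln p + ln A; empty/zero-mass classes contribute 0
  sum(-S[pos] / A[pos] + log(A[pos]))
}

#' Kapur's entropy of a thresholded histogram
#'
#' The objective maximized by the threshold search: the sum over classes of
#' the Shannon entropy of the class-normalized histogram segment,
#' \deqn{F = \sum_i H_i, \quad
#'       H_i = -\sum_{j \in class_i} \frac{p_j}{A_i}\ln\frac{p_j}{A_i},}
#' with \eqn{A_i} the probability mass of class i. Natural log; empty classes
#' and zero-probability levels contribute nothing.
#'
#' @param hist numeric vector of 256 probabilities summing to 1.
#' @param thresholds sorted integer vector in \[0, 255\]; may be empty (the
#'   entropy of the whole histogram) and may contain duplicates.
#' @return non-negative scalar.
#' @examples
#' u <- rep(1 / 256, 256)
#' kapurFitness(u, 127)   # 2 * log(128)
#' @export
kapurFitness <- function(hist, thresholds) {
  assertHistogram(hist)
  assertThresholds(thresholds)
  kapurEval(kapurCumsums(hist), as.integer(thresholds))
}

#' Exhaustive-search optimal thresholds for small instances
#'
#' Enumerates every non-decreasing k-tuple of gray levels in
#' `[0, maxLevel]` and returns the tuple maximizing [kapurFitness()]. Serves
#' as the ground-truth oracle for the stochastic optimizer. Ties are broken
#' toward the lexicographically smallest tuple (the first one enumerated).
#'
#' @param hist 256-bin probability histogram.
#' @param k number of thresholds (>= 0).
#' @param maxLevel largest gray level to consider (default 255).
#' @param limit refuse instances with more than this many candidate tuples.
#' @return list with `thresholds` (integer vector) and `fitness`.
#' @export
exhaustiveOptimum <- function(hist, k, maxLevel = 255L, limit = 250000) {
  assertHistogram(hist)
  if (k < 0 || k != floor(k)) stop("k must be a non-negative integer")
  cs <- kapurCumsums(hist)
  if (k == 0)
    return(list(thresholds = integer(0), fitness = kapurEval(cs, integer(0))))
  n <- maxLevel + 1L
  ncand <- choose(n + k - 1, k)
  if (ncand > limit)
    stop(sprintf("instance too large: %.0f candidate tuples exceed the limit of %.0f",
                 ncand, limit))
  # non-decreasing k-tuples from 0..maxLevel via strictly-increasing
  # combinations of 0..maxLevel+k-1 shifted back by 0..k-1
  combos <- utils::combn(seq_len(n + k - 1L) - 1L, k) - (seq_len(k) - 1L)
  best <- -Inf; bestT <- NULL
  for (j in seq_len(ncol(combos))) {
    f <- kapurEval(cs, combos[, j])
    if (f > best) { best <- f; bestT <- combos[, j] }
  }
  list(thresholds = as.integer(bestT), fitness = best)
}

#' Serialize / read a histogram as 256-line plain text
#'
#' @param hist 256 probabilities.
#' @param path file path.
#' @return `readHistogram` returns the numeric vector; `writeHistogram` the
#'   path, invisibly.
#' @export
writeHistogram <- function(hist, path) {
  assertHistogram(hist)
  writeLines(format(hist, digits = 17, scientific = TRUE, trim = TRUE), path)
  invisible(path)
}

#' @rdname writeHistogram
#' @export
readHistogram <- function(path) {
  p <- as.numeric(readLines(path))
  assertHistogram(p)
  p
}
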