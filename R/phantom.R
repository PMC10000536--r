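# Deterministic synthetic fixtures: piecewise-constant tumor phantoms with
# ground truth, and Gaussian-mixture histograms as optimizer landscapes.

discMask <- function(h, w, center, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  matrix(as.integer((rows - center[1])^2 + (cols - center[2])^2 <= radius^2),
         h, w)
}

#' Render a tumor phantom image with ground truth
#'
#' Builds a piecewise-constant image: concentric circular bands at the
#' lower class means, one bright disc (the "tumor") plus `speckCount` small
#' bright specks at the top class mean, then additive Gaussian noise
#' clipped to \[0, 255\] and rounded half-up. The layout mimics a
#' contrast-enhanced slice: a small bright structure at the centre (the
#' brightest background band, kept small so its noise tail cannot form
#' large spurious regions), a broad mid-gray tissue band holding the tumor,
#' and a dark surround. With zero noise the histogram support is exactly
#' the class means. The same spec (same seed) always renders bit-identical
#' output.
#'
#' @param spec a [phantomSpec()] object.
#' @return list with `image` (integer matrix) and `truth` (0/1 matrix of
#'   the tumor disc).
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  h <- spec@height; w <- spec@width
  means <- spec@classMeans
  nb <- length(means) - 1L               # background bands
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dist <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  # brightest band: a small central disc (10% of min dimension); remaining
  # bands split the radii up to 48.5% evenly; the darkest band is the rest
  m <- min(h, w)
  breaks <- c(seq(0.10, 0.485, length.out = max(1L, nb - 1L)) * m, Inf)
  band <- nb - findInterval(dist, breaks)       # nb = innermost = brightest
  band <- pmax(1L, band)
  img <- matrix(means[band], h, w)
  tumor <- discMask(h, w, spec@tumorCenter, spec@tumorRadius)
  img[tumor == 1L] <- means[nb + 1L]
  # bright specks away from the tumor
  placed <- 0L
  while (placed < spec@speckCount) {
    pr <- sample.int(h - 4L, 1L) + 2L
    pc <- sample.int(w - 4L, 1L) + 2L
    if (sqrt((pr - spec@tumorCenter[1])^2 + (pc - spec@tumorCenter[2])^2) <
        spec@tumorRadius + 12) next
    img[pr + c(0L, 0L, 1L), pc + c(0L, 1L, 0L)] <- means[nb + 1L]
    placed <- placed + 1L
  }
  if (spec@noiseSigma > 0) {
    img <- img + stats::rnorm(h * w, 0, spec@noiseSigma)
  }
  img <- matrix(as.integer(roundHalfUp(pmin(pmax(img, 0), 255))), h, w)
  list(image = img, truth = tumor)
}

#' Discretized Gaussian-mixture histogram
#'
#' A smooth multi-modal test landscape for the threshold optimizer: mixture
#' densities evaluated at the 256 gray levels and renormalized to sum to 1.
#' Densities below 1e-12 are truncated to exact zero so the result behaves
#' like a finite-sample histogram: Kapur's entropy is degenerate on classes
#' of vanishing-but-nonzero mass (they contribute full normalized entropy
#' at no cost), which no histogram of a real image can exhibit.
#'
#' @param weights non-negative mixture weights summing to 1.
#' @param means,sigmas component means and standard deviations (sigmas > 0,
#'   recycled).
#' @return numeric vector of 256 probabilities.
#' @export
makeMixtureHistogram <- function(weights, means, sigmas) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  sigmas <- rep_len(sigmas, length(weights))
  if (any(sigmas <= 0)) stop("sigmas must be > 0")
  j <- 0:255
  p <- rep(0, 256)
  for (i in seq_along(weights))
    p <- p + weights[i] * stats::dnorm(j, means[i], sigmas[i])
  p[p < 1e-12] <- 0
  if (sum(p) == 0) stop("degenerate mixture: zero mass on [0, 255]")
  p / sum(p)
}
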