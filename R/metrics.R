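# Reconstruction / overlap quality metrics and rerun statistics.

assertSameShape <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    stop("images must be matrices of identical shape")
  invisible(TRUE)
}

#' Mean squared error between two images
#'
#' @param a,b integer matrices of identical shape.
#' @return mean over pixels of the squared intensity difference.
#' @export
imgMSE <- function(a, b) {
  assertSameShape(a, b)
  mean((as.numeric(a) - as.numeric(b))^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(255^2 / MSE)`; identical images give `Inf`.
#'
#' @param a,b integer matrices of identical shape.
#' @return PSNR in dB.
#' @export
imgPSNR <- function(a, b) {
  m <- imgMSE(a, b)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with the canonical parameterization: 11x11 Gaussian
#' window with sigma 1.5, K1 = 0.01, K2 = 0.03, dynamic range L = 255.
#' Local statistics use valid windows only (a 5-pixel border is cropped),
#' so both image dimensions must be at least the window size.
#'
#' @param a,b integer matrices of identical shape, min dimension >= 11.
#' @param K1,K2 stability constants.
#' @param sigma window Gaussian sigma.
#' @param win window side length (odd).
#' @return scalar in \[-1, 1\]; 1 iff the images are identical.
#' @export
imgSSIM <- function(a, b, K1 = 0.01, K2 = 0.03, sigma = 1.5, win = 11L) {
  assertSameShape(a, b)
  if (min(dim(a)) < win)
    stop(sprintf("image smaller than the %dx%d SSIM window; reduce 'win'", win, win))
  L <- 255
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  r <- (win - 1L) / 2L
  idx <- seq(-r, r)
  g <- exp(-idx^2 / (2 * sigma^2))
  kern <- outer(g, g); kern <- kern / sum(kern)
  x <- matrix(as.numeric(a), nrow(a)); y <- matrix(as.numeric(b), nrow(b))
  f <- function(z) EBImage::filter2(z, kern, boundary = "replicate")
  mux <- f(x); muy <- f(y)
  sxx <- f(x * x) - mux^2
  syy <- f(y * y) - muy^2
  sxy <- f(x * y) - mux * muy
  ssimMap <- ((2 * mux * muy + C1) * (2 * sxy + C2)) /
    ((mux^2 + muy^2 + C1) * (sxx + syy + C2))
  core <- ssimMap[(r + 1):(nrow(a) - r), (r + 1):(ncol(a) - r), drop = FALSE]
  mean(core)
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks give 1 by convention.
#'
#' @param a,b 0/1 integer matrices of identical shape.
#' @return scalar in \[0, 1\].
#' @export
diceCoef <- function(a, b) {
  assertSameShape(a, b)
  assertMask(a); assertMask(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Best / mean / standard deviation over rerun fitness values
#'
#' The standard deviation is the population form (divide by n).
#'
#' @param fitness non-empty numeric vector of per-rerun best fitness.
#' @return named list with `best`, `mean`, `sd`.
#' @export
rerunStats <- function(fitness) {
  if (!length(fitness)) stop("fitness list must be non-empty")
  m <- mean(fitness)
  list(best = max(fitness), mean = m,
       sd = sqrt(mean((fitness - m)^2)))
}
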