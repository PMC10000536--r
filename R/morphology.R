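# The post-processing chain applied to the binary segmented image:
# Canny edges -> disc dilation -> boundary/region bookkeeping ->
# small-region removal -> hole filling -> target-region selection.
#
# Dilation and 2-D convolution go through EBImage; labelling, hole filling
# and Canny itself are implemented here (they need the package's 4/8
# connectivity conventions, which EBImage does not expose).

# Euclidean disc kernel: pixel (dr, dc) included iff dr^2 + dc^2 <= r^2
discKernel <- function(radius) {
  r <- as.integer(radius)
  d <- 2L * r + 1L
  idx <- seq(-r, r)
  k <- outer(idx^2, idx^2, "+") <= radius^2
  matrix(as.numeric(k), d, d)
}

gaussianKernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  idx <- seq(-r, r)
  g <- exp(-idx^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

conv2 <- function(x, kern) {
  # replicated borders; EBImage::filter2 correlates, symmetric kernels only
  EBImage::filter2(x, kern, boundary = "replicate")
}

#' Canny edge map of a binary mask
#'
#' Standard Canny on the 0/1 raster: Gaussian smoothing at
#' `control@cannySigma`, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, then hysteresis with thresholds
#' `cannyLow`/`cannyHigh` relative to the maximum gradient magnitude (weak
#' edges survive only when 8-connected to a strong edge).
#'
#' @param mask 0/1 integer matrix.
#' @param control a [morphControl()] object.
#' @return 0/1 integer matrix of edge pixels.
#' @export
cannyEdges <- function(mask, control = morphControl()) {
  assertMask(mask)
  h <- nrow(mask); w <- ncol(mask)
  sm <- conv2(matrix(as.numeric(mask), h, w), gaussianKernel(control@cannySigma))
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/dcol
  sy <- t(sx)                                            # d/drow
  gx <- conv2(sm, sx)
  gy <- conv2(sm, sy)
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  # constant masks have zero gradient up to FFT round-off; a genuine 0/1
  # step always produces magnitudes of order 1
  if (mx < 1e-6) return(matrix(0L, h, w))
  # quantize gradient direction into 4 sectors; the comparison step follows
  # the gradient vector (dc = gx, dr = gy): 0 = along columns, 1 = main
  # diagonal, 2 = along rows, 3 = anti-diagonal
  ang <- atan2(gy, gx)
  sector <- floor(((ang + pi) / pi * 4 + 0.5)) %% 4
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mag
  shift <- function(dr, dc) pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  pairs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(-1, 1))
  for (s in 0:3) {
    sel <- sector == s
    d <- pairs[[as.character(s)]]
    n1[sel] <- shift(d[1], d[2])[sel]
    n2[sel] <- shift(-d[1], -d[2])[sel]
  }
  nms <- mag >= n1 & mag >= n2
  strong <- nms & (mag >= control@cannyHigh * mx)
  weak <- nms & (mag >= control@cannyLow * mx)
  if (!any(strong)) return(matrix(0L, h, w))
  lab <- labelComponents(matrix(as.integer(weak), h, w), connectivity = 8)
  keep <- unique(lab[strong])
  out <- matrix(as.integer(lab > 0L & lab %in% keep), h, w)
  out
}

#' Dilate a binary mask by a Euclidean disc
#'
#' A pixel of the output is set iff any input foreground pixel lies within
#' Euclidean distance `radius` of it.
#'
#' @param mask 0/1 integer matrix.
#' @param radius disc radius in pixels (>= 1).
#' @return 0/1 integer matrix, a superset of the input.
#' @export
dilateMask <- function(mask, radius = 2) {
  assertMask(mask)
  if (radius < 1) stop("radius must be >= 1")
  out <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                         discKernel(radius))
  matrix(as.integer(out > 0.5), nrow(mask), ncol(mask))
}

#' Remove small connected components
#'
#' Deletes every foreground component whose pixel count is below `minArea`;
#' larger components pass through untouched.
#'
#' @param mask 0/1 integer matrix.
#' @param minArea minimum surviving component area in pixels.
#' @param connectivity 4 or 8.
#' @return 0/1 integer matrix.
#' @export
removeSmallRegions <- function(mask, minArea, connectivity = 8) {
  assertMask(mask)
  if (minArea < 0) stop("minArea must be >= 0")
  lab <- labelComponents(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- componentSizes(lab)
  keep <- which(sizes >= minArea)
  matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
}

#' Fill enclosed holes of a binary mask
#'
#' Background components not connected to the image border are set to
#' foreground. The background flood fill uses 4-connectivity (the standard
#' dual of 8-connected foreground).
#'
#' @param mask 0/1 integer matrix.
#' @return 0/1 integer matrix.
#' @export
fillHoles <- function(mask) {
  assertMask(mask)
  bg <- matrix(as.integer(mask == 0L), nrow(mask), ncol(mask))
  lab <- labelComponents(bg, connectivity = 4)
  h <- nrow(mask); w <- ncol(mask)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border <- border[border > 0L]
  hole <- lab > 0L & !(lab %in% border)
  out <- mask
  out[hole] <- 1L
  out
}

#' Select the target region from a processed mask
#'
#' `selection = "largest"` keeps only the largest connected component (ties
#' broken toward the component whose first pixel comes first in row-major
#' raster order); `"all"` returns the mask unchanged. An empty mask is
#' returned empty with a warning.
#'
#' @param mask 0/1 integer matrix.
#' @param selection `"largest"` or `"all"`.
#' @param connectivity 4 or 8.
#' @return 0/1 integer matrix.
#' @export
selectRegion <- function(mask, selection = c("largest", "all"), connectivity = 8) {
  selection <- match.arg(selection)
  assertMask(mask)
  if (selection == "all") return(mask)
  lab <- labelComponents(mask, connectivity)
  if (max(lab) == 0L) {
    warning("empty mask: no region to select")
    return(mask)
  }
  sizes <- componentSizes(lab)
  best <- which.max(sizes)      # ties -> smallest label = first in raster scan
  matrix(as.integer(lab == best), nrow(mask), ncol(mask))
}

#' Full morphological post-processing chain
#'
#' Applies, in order: [cannyEdges()], [dilateMask()], boundary/region
#' labelling, [removeSmallRegions()], [fillHoles()] and [selectRegion()].
#' On a mask containing one solid blob plus small specks this recovers the
#' blob: its dilated edge loop closes, the speck remnants fall below
#' `minArea`, and the enclosed interior is filled.
#'
#' @param mask 0/1 integer matrix (the binary segmented image).
#' @param control a [morphControl()] object; `minArea = NA` resolves to 1%
#'   of the image area.
#' @return 0/1 integer matrix containing the selected target region.
#' @export
postprocessMask <- function(mask, control = morphControl()) {
  assertMask(mask)
  minArea <- control@minArea
  if (is.na(minArea)) minArea <- ceiling(0.01 * length(mask))
  edges <- cannyEdges(mask, control)
  grown <- dilateMask(edges, control@dilationRadius)
  grown <- removeSmallRegions(grown, minArea, control@connectivity)
  filled <- fillHoles(grown)
  selectRegion(filled, control@selection, control@connectivity)
}
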