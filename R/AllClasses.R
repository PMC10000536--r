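#' @import methods
NULL

#' Control parameters for the bald eagle search optimizer
#'
#' S4 container for every tunable of the BES/DOBES threshold search.
#' Construct with [besControl()], which validates ranges.
#'
#' @slot populationSize number of search agents N.
#' @slot maxIterations iterations of the select/search/swoop loop per rerun.
#' @slot reruns independent restarts; rerun j uses seed `seed + j - 1`.
#' @slot alphaSelect select-phase step scale, in \[1.5, 2\].
#' @slot alphaSpiral spiral angle scale, in \[5, 10\].
#' @slot searchCycles spiral radius increment R, in \[0.5, 2\].
#' @slot c1,c2 swoop-phase centre weights, each in \[1, 2\].
#' @slot dolWeight dynamic-opposite step weight w (> 0).
#' @slot seed base RNG seed.
#' @slot lower,upper per-dimension box bounds of the search space.
#' @export
setClass("BESControl", representation(
  populationSize = "numeric",
  maxIterations  = "numeric",
  reruns         = "numeric",
  alphaSelect    = "numeric",
  alphaSpiral    = "numeric",
  searchCycles   = "numeric",
  c1             = "numeric",
  c2             = "numeric",
  dolWeight      = "numeric",
  seed           = "numeric",
  lower          = "numeric",
  upper          = "numeric"
))

setValidity("BESControl", function(object) {
  msgs <- character()
  chk <- function(cond, msg) if (!cond) msgs <<- c(msgs, msg)
  chk(object@populationSize >= 2, "populationSize must be >= 2")
  chk(object@maxIterations >= 1, "maxIterations must be >= 1")
  chk(object@reruns >= 1, "reruns must be >= 1")
  chk(object@alphaSelect >= 1.5 && object@alphaSelect <= 2,
      "alphaSelect must lie in [1.5, 2]")
  chk(object@alphaSpiral >= 5 && object@alphaSpiral <= 10,
      "alphaSpiral must lie in [5, 10]")
  chk(object@searchCycles >= 0.5 && object@searchCycles <= 2,
      "searchCycles must lie in [0.5, 2]")
  chk(object@c1 >= 1 && object@c1 <= 2, "c1 must lie in [1, 2]")
  chk(object@c2 >= 1 && object@c2 <= 2, "c2 must lie in [1, 2]")
  chk(object@dolWeight > 0, "dolWeight must be > 0")
  chk(object@lower <= object@upper, "lower must be <= upper")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn BESControl-class constructor with the optimizer defaults:
#'   30 agents, 100 iterations, 10 reruns, bounds \[0, 255\].
#' @param populationSize,maxIterations,reruns,alphaSelect,alphaSpiral,searchCycles,c1,c2,dolWeight,seed,lower,upper
#'   see the slot documentation.
#' @return a validated `BESControl` object.
#' @export
besControl <- function(populationSize = 30, maxIterations = 100, reruns = 10,
                       alphaSelect = 2, alphaSpiral = 10, searchCycles = 1.5,
                       c1 = 2, c2 = 2, dolWeight = 3, seed = 1,
                       lower = 0, upper = 255) {
  new("BESControl",
      populationSize = as.numeric(populationSize),
      maxIterations = as.numeric(maxIterations),
      reruns = as.numeric(reruns),
      alphaSelect = alphaSelect, alphaSpiral = alphaSpiral,
      searchCycles = searchCycles, c1 = c1, c2 = c2,
      dolWeight = dolWeight, seed = as.numeric(seed),
      lower = lower, upper = upper)
}

setMethod("show", "BESControl", function(object) {
  cat("BESControl: N =", object@populationSize,
      "| iterations =", object@maxIterations,
      "| reruns =", object@reruns, "\n")
  cat("  alphaSelect =", object@alphaSelect,
      ", alphaSpiral =", object@alphaSpiral,
      ", R =", object@searchCycles,
      ", c1 =", object@c1, ", c2 =", object@c2, "\n")
  cat("  DOL weight =", object@dolWeight,
      "| bounds = [", object@lower, ",", object@upper, "]",
      "| seed =", object@seed, "\n")
})

#' Result of a threshold-optimization run
#'
#' Returned by [runDOBES()] and [runBES()]. The convergence slot is the
#' best-so-far fitness per iteration of the best rerun; elitism makes it
#' non-decreasing and its last entry equals `bestFitness`.
#'
#' @slot thresholds integer gray levels, sorted non-decreasing.
#' @slot fitness Kapur entropy of the best threshold set found.
#' @slot convergence best-so-far fitness curve of the best rerun.
#' @slot rerunFitness best fitness attained in each rerun.
#' @slot algorithm `"DOBES"` or `"BES"`.
#' @slot control the `BESControl` used.
#' @export
setClass("ThresholdFit", representation(
  thresholds   = "integer",
  fitness      = "numeric",
  convergence  = "numeric",
  rerunFitness = "numeric",
  algorithm    = "character",
  control      = "BESControl"
))

setValidity("ThresholdFit", function(object) {
  msgs <- character()
  t <- object@thresholds
  if (length(t) && (is.unsorted(t) || any(t < 0L) || any(t > 255L)))
    msgs <- c(msgs, "thresholds must be sorted within [0, 255]")
  if (length(object@convergence)) {
    if (any(diff(object@convergence) < 0))
      msgs <- c(msgs, "convergence curve must be non-decreasing")
    if (abs(object@fitness - object@convergence[length(object@convergence)]) > 1e-12)
      msgs <- c(msgs, "fitness must equal the final convergence entry")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ThresholdFit", function(object) {
  cat(object@algorithm, "threshold fit\n")
  cat("  thresholds: [", paste(object@thresholds, collapse = ", "), "]\n")
  cat("  Kapur entropy:", format(object@fitness, digits = 8), "\n")
  cat("  reruns:", length(object@rerunFitness),
      "| mean fitness:", format(mean(object@rerunFitness), digits = 8), "\n")
})

#' @describeIn ThresholdFit-class best threshold set found.
#' @param object a `ThresholdFit`.
#' @export
setGeneric("bestThresholds", function(object) standardGeneric("bestThresholds"))
#' @rdname ThresholdFit-class
#' @export
setMethod("bestThresholds", "ThresholdFit", function(object) object@thresholds)

#' @describeIn ThresholdFit-class best Kapur entropy found.
#' @export
setGeneric("bestFitness", function(object) standardGeneric("bestFitness"))
#' @rdname ThresholdFit-class
#' @export
setMethod("bestFitness", "ThresholdFit", function(object) object@fitness)

#' @describeIn ThresholdFit-class per-iteration best-so-far fitness of the
#'   best rerun.
#' @export
setGeneric("convergence", function(object) standardGeneric("convergence"))
#' @rdname ThresholdFit-class
#' @export
setMethod("convergence", "ThresholdFit", function(object) object@convergence)

#' @describeIn ThresholdFit-class best fitness per rerun.
#' @export
setGeneric("rerunFitness", function(object) standardGeneric("rerunFitness"))
#' @rdname ThresholdFit-class
#' @export
setMethod("rerunFitness", "ThresholdFit", function(object) object@rerunFitness)

#' Control parameters for the morphological post-processing chain
#'
#' Construct with [morphControl()]. `minArea = NA` means 1% of the image
#' area, resolved when [postprocessMask()] sees the mask.
#'
#' @slot cannySigma Gaussian smoothing sigma (pixels) for edge detection.
#' @slot cannyLow,cannyHigh hysteresis thresholds, relative to the maximum
#'   gradient magnitude, in (0, 1) with low < high.
#' @slot dilationRadius Euclidean disc radius (pixels) for dilation.
#' @slot minArea components smaller than this many pixels are removed.
#' @slot connectivity 4 or 8, for foreground component labelling.
#' @slot selection `"largest"` keeps the largest component, `"all"` keeps all.
#' @export
setClass("MorphControl", representation(
  cannySigma     = "numeric",
  cannyLow       = "numeric",
  cannyHigh      = "numeric",
  dilationRadius = "numeric",
  minArea        = "numeric",
  connectivity   = "numeric",
  selection      = "character"
))

setValidity("MorphControl", function(object) {
  msgs <- character()
  if (object@cannySigma <= 0) msgs <- c(msgs, "cannySigma must be > 0")
  if (!(object@cannyLow > 0 && object@cannyHigh < 1 &&
        object@cannyLow < object@cannyHigh))
    msgs <- c(msgs, "need 0 < cannyLow < cannyHigh < 1")
  if (object@dilationRadius < 1) msgs <- c(msgs, "dilationRadius must be >= 1")
  if (!is.na(object@minArea) && object@minArea < 0)
    msgs <- c(msgs, "minArea must be >= 0")
  if (!object@connectivity %in% c(4, 8))
    msgs <- c(msgs, "connectivity must be 4 or 8")
  if (!object@selection %in% c("largest", "all"))
    msgs <- c(msgs, "selection must be 'largest' or 'all'")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MorphControl-class constructor with chain defaults.
#' @param cannySigma,cannyLow,cannyHigh,dilationRadius,minArea,connectivity,selection
#'   see the slot documentation.
#' @export
morphControl <- function(cannySigma = 1.0, cannyLow = 0.1, cannyHigh = 0.2,
                         dilationRadius = 2, minArea = NA_real_,
                         connectivity = 8, selection = "largest") {
  new("MorphControl", cannySigma = cannySigma, cannyLow = cannyLow,
      cannyHigh = cannyHigh, dilationRadius = as.numeric(dilationRadius),
      minArea = as.numeric(minArea), connectivity = as.numeric(connectivity),
      selection = selection)
}

setMethod("show", "MorphControl", function(object) {
  cat("MorphControl: Canny sigma =", object@cannySigma,
      "low/high =", object@cannyLow, "/", object@cannyHigh, "\n")
  cat("  dilation radius =", object@dilationRadius,
      "| minArea =", ifelse(is.na(object@minArea), "1% of image",
                            object@minArea),
      "| connectivity =", object@connectivity,
      "| selection =", object@selection, "\n")
})

#' Specification of a synthetic tumor phantom
#'
#' Construct with [phantomSpec()]; render with [makePhantom()]. The phantom
#' is a piecewise-constant image: concentric bands at the lower class means,
#' one bright disc (the "tumor") plus a few bright specks at the top class
#' mean, additive Gaussian noise clipped to \[0, 255\].
#'
#' @slot height,width image size in pixels.
#' @slot classMeans strictly increasing intensities in \[0, 255\]; the last
#'   one paints the tumor and specks, the others the background bands.
#' @slot tumorCenter (row, col) of the tumor disc centre.
#' @slot tumorRadius disc radius in pixels.
#' @slot speckCount number of small bright nuisance blobs.
#' @slot noiseSigma Gaussian intensity noise sigma (gray levels).
#' @slot seed RNG seed for noise and speck placement.
#' @export
setClass("PhantomSpec", representation(
  height      = "numeric",
  width       = "numeric",
  classMeans  = "numeric",
  tumorCenter = "numeric",
  tumorRadius = "numeric",
  speckCount  = "numeric",
  noiseSigma  = "numeric",
  seed        = "numeric"
))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  m <- object@classMeans
  if (length(m) < 2 || any(diff(m) <= 0) || any(m < 0) || any(m > 255))
    msgs <- c(msgs, "classMeans must be strictly increasing within [0, 255]")
  if (object@height < 8 || object@width < 8)
    msgs <- c(msgs, "phantom must be at least 8x8")
  ctr <- object@tumorCenter; r <- object@tumorRadius
  if (length(ctr) != 2) msgs <- c(msgs, "tumorCenter must be (row, col)")
  else if (ctr[1] - r < 1 || ctr[1] + r > object@height ||
           ctr[2] - r < 1 || ctr[2] + r > object@width)
    msgs <- c(msgs, "tumor disc must lie fully inside the image")
  if (object@tumorRadius < 1) msgs <- c(msgs, "tumorRadius must be >= 1")
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  if (object@speckCount < 0) msgs <- c(msgs, "speckCount must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PhantomSpec-class constructor. Defaults: 256x256, class means
#'   20/90/160/230, an off-centre radius-34 tumor in the mid-gray band,
#'   5 specks, noise sigma 5.
#' @param height,width,classMeans,tumorCenter,tumorRadius,speckCount,noiseSigma,seed
#'   see the slot documentation.
#' @export
phantomSpec <- function(height = 256, width = 256,
                        classMeans = c(20, 90, 160, 230),
                        tumorCenter = c(76, 188), tumorRadius = 34,
                        speckCount = 5, noiseSigma = 5, seed = 1) {
  new("PhantomSpec", height = as.numeric(height), width = as.numeric(width),
      classMeans = as.numeric(classMeans),
      tumorCenter = as.numeric(tumorCenter),
      tumorRadius = as.numeric(tumorRadius),
      speckCount = as.numeric(speckCount),
      noiseSigma = as.numeric(noiseSigma), seed = as.numeric(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@height, "x", object@width,
      "| class means:", paste(object@classMeans, collapse = ", "), "\n")
  cat("  tumor disc r =", object@tumorRadius, "at (",
      object@tumorCenter[1], ",", object@tumorCenter[2], ") |",
      object@speckCount, "specks | noise sigma =", object@noiseSigma,
      "| seed =", object@seed, "\n")
})
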