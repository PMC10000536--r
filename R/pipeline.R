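# The end-to-end hybrid pipeline and the benchmark driver behind the CLI.

#' Run the full hybrid segmentation pipeline
#'
#' Histogram -> threshold search ([runDOBES()] or [runBES()]) ->
#' threshold image ([quantizeImage()]) and binary segmented image
#' ([binarizeImage()]) -> morphological post-processing
#' ([postprocessMask()]).
#'
#' @param image integer matrix in \[0, 255\], or a path readable by
#'   [readGrayImage()].
#' @param k number of thresholds (default 3).
#' @param optimizer `"dobes"` or `"bes"`.
#' @param control a [besControl()] object.
#' @param morph a [morphControl()] object.
#' @param foreground class indices binarized as foreground; default the
#'   brightest class.
#' @param quantizeMode `"class_mean"` or `"class_floor"`.
#' @param truth optional 0/1 ground-truth mask; adds a Dice entry.
#' @param outDir optional directory; when given, the threshold image,
#'   binary mask, final mask and a JSON report are written there.
#' @return list with `fit` (a [ThresholdFit-class]), `thresholdImage`,
#'   `binaryMask`, `finalMask`, and `metrics` (mse/psnr/ssim of the
#'   threshold image vs the input, rerun statistics, and dice if `truth`
#'   was supplied).
#' @export
segmentImage <- function(image, k = 3, optimizer = c("dobes", "bes"),
                         control = besControl(), morph = morphControl(),
                         foreground = NULL,
                         quantizeMode = "class_mean",
                         truth = NULL, outDir = NULL) {
  optimizer <- match.arg(optimizer)
  if (is.character(image)) image <- readGrayImage(image)
  assertGrayImage(image)
  if (k < 1) stop("k must be >= 1")
  hist <- computeHistogram(image)
  fit <- if (optimizer == "dobes") runDOBES(hist, k, control)
         else runBES(hist, k, control)
  thr <- bestThresholds(fit)
  timg <- quantizeImage(image, thr, quantizeMode)
  bmask <- binarizeImage(image, thr, foreground)
  fmask <- postprocessMask(bmask, morph)
  stats <- rerunStats(rerunFitness(fit))
  metrics <- list(mse = imgMSE(image, timg),
                  psnr = imgPSNR(image, timg),
                  ssim = imgSSIM(image, timg),
                  bestFitness = stats$best,
                  meanFitness = stats$mean,
                  sdFitness = stats$sd)
  if (!is.null(truth)) metrics$dice <- diceCoef(fmask, truth)
  res <- list(fit = fit, thresholdImage = timg, binaryMask = bmask,
              finalMask = fmask, metrics = metrics)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeGrayPNG(timg, file.path(outDir, "threshold_image.png"))
    writeGrayPNG(bmask, file.path(outDir, "binary_mask.png"))
    writeGrayPNG(fmask, file.path(outDir, "final_mask.png"))
    report <- list(algorithm = fit@algorithm, k = k,
                   seed = control@seed,
                   thresholds = thr, fitness = bestFitness(fit),
                   convergence = convergence(fit),
                   rerunFitness = rerunFitness(fit),
                   metrics = metrics)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Benchmark a set of images with both optimizers
#'
#' Runs DOBES and BES on each image and tabulates the per-image fitness
#' statistics and reconstruction metrics, one row per image x optimizer.
#'
#' @param images named list of integer matrices, or a character vector of
#'   image paths.
#' @param k number of thresholds.
#' @param control a [besControl()] object; the per-image seed is taken from
#'   it.
#' @return data.frame with columns image, algo, levels, best, mean, sd,
#'   mse, psnr, ssim.
#' @export
benchmarkImages <- function(images, k = 8, control = besControl()) {
  if (is.character(images)) {
    if (!length(images)) stop("no images supplied")
    nm <- tools::file_path_sans_ext(basename(images))
    images <- stats::setNames(lapply(images, readGrayImage), nm)
  }
  if (!length(images)) stop("no images supplied")
  if (is.null(names(images))) names(images) <- paste0("image", seq_along(images))
  rows <- list()
  for (nm in names(images)) {
    img <- images[[nm]]
    hist <- computeHistogram(img)
    for (algo in c("dobes", "bes")) {
      fit <- if (algo == "dobes") runDOBES(hist, k, control)
             else runBES(hist, k, control)
      timg <- quantizeImage(img, bestThresholds(fit))
      st <- rerunStats(rerunFitness(fit))
      rows[[length(rows) + 1L]] <- data.frame(
        image = nm, algo = toupper(algo), levels = k,
        best = st$best, mean = st$mean, sd = st$sd,
        mse = imgMSE(img, timg), psnr = imgPSNR(img, timg),
        ssim = imgSSIM(img, timg))
    }
  }
  do.call(rbind, rows)
}

#' Kapur entropy of an image at a fixed threshold set
#'
#' Checking helper for published benchmark results: computes the histogram
#' of the image at `path` and evaluates [kapurFitness()] at the given
#' (already chosen) thresholds, without running any optimizer.
#'
#' @param path image path.
#' @param thresholds sorted integer thresholds.
#' @return scalar Kapur entropy.
#' @export
benchmarkFitnessAtThresholds <- function(path, thresholds) {
  img <- readGrayImage(path)
  kapurFitness(computeHistogram(img), thresholds)
}
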