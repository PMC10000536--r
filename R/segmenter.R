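# Threshold image and binary segmented image (the two intermediate
# products between the optimizer and the morphology chain).

# class index of each gray level 0..255 under the lower-class convention:
# class(j) = number of thresholds strictly below j
classIndexLUT <- function(thresholds) {
  j <- 0:255
  vapply(j, function(g) sum(thresholds < g), integer(1))
}

#' Quantize an image to per-class representative gray levels
#'
#' Replaces every pixel by a representative of its threshold class. Mode
#' `class_mean` uses the round-half-up intensity-weighted mean of the
#' class's histogram mass (minimizing MSE against the input); classes with
#' no mass fall back to the midpoint of their interval. Mode `class_floor`
#' uses the lowest gray level of the interval.
#'
#' @param image integer matrix in \[0, 255\].
#' @param thresholds sorted integer thresholds (possibly empty).
#' @param mode `"class_mean"` or `"class_floor"`.
#' @return integer matrix of the same shape.
#' @export
quantizeImage <- function(image, thresholds, mode = c("class_mean", "class_floor")) {
  mode <- match.arg(mode)
  assertGrayImage(image)
  assertThresholds(thresholds)
  part <- partitionClasses(thresholds)
  hist <- computeHistogram(image)
  rep_ <- integer(nrow(part))
  for (i in seq_len(nrow(part))) {
    lo <- part$lo[i]; hi <- part$hi[i]
    if (lo > hi) { rep_[i] <- NA_integer_; next }     # empty class
    if (mode == "class_floor") { rep_[i] <- lo; next }
    mass <- hist[(lo:hi) + 1L]
    rep_[i] <- if (sum(mass) > 0)
      as.integer(roundHalfUp(sum((lo:hi) * mass) / sum(mass)))
    else as.integer(roundHalfUp((lo + hi) / 2))
  }
  cls <- classIndexLUT(thresholds)
  out <- matrix(rep_[cls[image + 1L] + 1L], nrow(image), ncol(image))
  storage.mode(out) <- "integer"
  out
}

#' Binary segmented image from a threshold class selection
#'
#' Marks as foreground every pixel whose threshold class index is in
#' `foreground`. Class indices run 0..k with k = number of thresholds; the
#' default selects the brightest class only, matching a bright compact
#' target on a darker background.
#'
#' @param image integer matrix in \[0, 255\].
#' @param thresholds sorted integer thresholds.
#' @param foreground integer set of class indices in 0..k.
#' @return integer matrix of 0/1, same shape as `image`.
#' @export
binarizeImage <- function(image, thresholds, foreground = NULL) {
  assertGrayImage(image)
  assertThresholds(thresholds)
  k <- length(thresholds)
  if (is.null(foreground)) foreground <- k
  if (length(foreground) == 0) stop("foreground class set must not be empty")
  if (any(foreground < 0) || any(foreground > k))
    stop("foreground class indices must lie in 0..k")
  cls <- classIndexLUT(thresholds)
  out <- matrix(as.integer(cls[image + 1L] %in% foreground),
                nrow(image), ncol(image))
  out
}
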