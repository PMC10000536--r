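# Raster I/O. PNG, TIFF and JPEG are read through their dedicated
# packages; RGB inputs collapse to 8-bit luminance with the ITU-R BT.601
# weights (0.299, 0.587, 0.114) and round-half-up, so results are
# bit-exact across platforms.

#' Read an image as an 8-bit grayscale matrix
#'
#' @param path a PNG, TIFF or JPEG file.
#' @return integer matrix with values in \[0, 255\].
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' (use PNG, TIFF or JPEG): ", path))
  toLuminance(arr)
}

#' Convert a decoded raster array to 8-bit luminance
#'
#' @param arr numeric array in \[0, 1\] as returned by the png/tiff/jpeg
#'   readers; 2-D (gray), or 3-D with 2 (gray+alpha), 3 (RGB) or 4 (RGBA)
#'   channels. Alpha is ignored.
#' @return integer matrix in \[0, 255\].
#' @export
toLuminance <- function(arr) {
  ch8 <- function(x) roundHalfUp(x * 255)
  if (length(dim(arr)) == 2) {
    lum <- ch8(arr)
  } else if (length(dim(arr)) == 3 && dim(arr)[3] %in% c(2L)) {
    lum <- ch8(arr[, , 1])
  } else if (length(dim(arr)) == 3 && dim(arr)[3] %in% c(3L, 4L)) {
    lum <- roundHalfUp(0.299 * ch8(arr[, , 1]) + 0.587 * ch8(arr[, , 2]) +
                         0.114 * ch8(arr[, , 3]))
  } else {
    stop("unsupported raster layout: dims ", paste(dim(arr), collapse = "x"))
  }
  out <- matrix(as.integer(lum), dim(arr)[1], dim(arr)[2])
  out
}

#' Write an image or mask as 8-bit PNG
#'
#' Masks (0/1) are scaled to 0/255 so they are viewable.
#'
#' @param image integer matrix in \[0, 255\], or a 0/1 mask.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGrayPNG <- function(image, path) {
  if (all(image %in% c(0L, 1L)) && max(image) <= 1) image <- image * 255L
  png::writePNG(image / 255, path)
  invisible(path)
}
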