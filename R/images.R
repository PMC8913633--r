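# Image file I/O and resizing. Images are [H, W, 3] arrays in [0, 1].

#' Read / write an RGB image
#'
#' PNG files are read into `[height, width, 3]` arrays in `[0, 1]`;
#' grayscale files are replicated to three channels and alpha channels are
#' dropped.
#'
#' @param path PNG file path.
#' @param image `[H, W, 3]` array in `[0, 1]`.
#' @return `readImageRGB` returns the image array; `writeImageRGB` returns
#'   `path` invisibly.
#' @export
readImageRGB <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  img
}

#' @rdname readImageRGB
#' @export
writeImageRGB <- function(image, path) {
  .assertImage(image)
  png::writePNG(.clamp01(image), path)
  invisible(path)
}

#' Resize an RGB image with bilinear interpolation
#'
#' @param image `[H, W, 3]` array.
#' @param height,width output size in pixels.
#' @return resized `[height, width, 3]` array.
#' @export
resizeImage <- function(image, height, width) {
  .assertImage(image)
  eb <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(eb, w = width, h = height)
  aperm(EBImage::imageData(out), c(2, 1, 3))
}
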