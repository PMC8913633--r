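# Circular illusion-like designs: tile a patch, append a white spacer, warp
# to a ring by polar conversion, compose the probe stimulus.

#' White-spacer height for a tiled ring design
#'
#' For a patch of width `x` and height `y` repeated `nS` times, the strip
#' length `nS * x` must equal the circumference `2 * pi * r` of a ring with
#' radius `r = h + y / 2`, giving `h = ((nS * x) / pi - y) / 2`; decimal
#' values are rounded down.
#'
#' @param x,y patch width and height in pixels (positive integers).
#' @param nS number of repetitions (default 20).
#' @return integer spacer height `h`.
#' @examples
#' spacerHeight(9, 26)   # 15
#' spacerHeight(8, 18)   # 16
#' @export
spacerHeight <- function(x, y, nS = 20L) {
  stopifnot(x >= 1, y >= 1, nS >= 1)
  u <- (nS * x / pi - y) / 2
  if (u < 0)
    stop("patch is too tall for ", nS, " repetitions: spacer height would be ",
         "negative", call. = FALSE)
  as.integer(floor(u))
}

#' Tile a patch horizontally
#'
#' @param patch `[y, x, 3]` image patch.
#' @param nS number of repetitions.
#' @return `[y, nS * x, 3]` strip; column `c` equals patch column
#'   `c mod x`.
#' @export
tilePatch <- function(patch, nS = 20L) {
  .assertImage(patch)
  stopifnot(nS >= 1)
  patch[, rep(seq_len(dim(patch)[2]), nS), , drop = FALSE]
}

#' Append a white spacer band below a strip
#'
#' @param strip `[y, W, 3]` image.
#' @param h spacer height in pixels (>= 0); the white band spans the full
#'   strip width.
#' @return `[y + h, W, 3]` image with the bottom `h` rows pure white.
#' @export
addSpacer <- function(strip, h) {
  .assertImage(strip)
  stopifnot(h >= 0)
  if (h == 0) return(strip)
  d <- dim(strip)
  out <- array(1, c(d[1] + h, d[2], 3))
  out[seq_len(d[1]), , ] <- strip
  out
}

#' Left-right mirrored variant of a patch
#'
#' @param patch image array.
#' @return the horizontal flip; applying it twice is the identity.
#' @export
mirrorVariant <- function(patch) {
  .assertImage(patch)
  patch[, rev(seq_len(dim(patch)[2])), , drop = FALSE]
}

#' Polar-warp a strip into a ring
#'
#' Inverse-maps each output pixel to strip coordinates: the horizontal axis
#' of the strip maps linearly to angle over `[0, 2 * pi)` (origin at the
#' 3-o'clock position, increasing counterclockwise) and the vertical axis to
#' radius, with the strip's top row at the outer rim and its bottom row at
#' radius `innerRadius` (in strip-pixel units) toward the centre. The disk of
#' source radius `innerRadius + strip height` fills the square output;
#' everything outside the annulus is white. Sampling is bilinear (wrapping in
#' angle) or nearest-neighbour.
#'
#' @param strip `[H, W, 3]` extended strip (tiled patch + spacer).
#' @param outSize side of the square output image (default 1024).
#' @param innerRadius radius assigned to the strip's bottom row, in source
#'   pixels (default 0: the strip reaches the centre).
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return `[outSize, outSize, 3]` ring image.
#' @export
polarRing <- function(strip, outSize = 1024L, innerRadius = 0,
                      interpolation = c("bilinear", "nearest")) {
  .assertImage(strip)
  interpolation <- match.arg(interpolation)
  d <- dim(strip); Hs <- d[1]; Ws <- d[2]
  if (outSize < 2 * (Hs + innerRadius))
    warning("outSize ", outSize, " is below the resolution of the strip (",
            2 * (Hs + innerRadius), "); the ring will be undersampled")
  ctr <- (outSize + 1) / 2
  scale <- (outSize / 2) / (innerRadius + Hs)
  xs <- matrix(seq_len(outSize), outSize, outSize, byrow = TRUE) - ctr
  ys <- matrix(seq_len(outSize), outSize, outSize) - ctr
  rho <- sqrt(xs^2 + ys^2) / scale
  theta <- atan2(-ys, xs) %% (2 * pi)
  ucol <- theta / (2 * pi) * Ws + 0.5
  vrow <- Hs - (rho - innerRadius) + 0.5
  inside <- rho >= innerRadius & rho <= innerRadius + Hs
  if (interpolation == "nearest") {
    ucol <- ((round(ucol) - 1) %% Ws) + 1
    vrow <- pmin(pmax(round(vrow), 1), Hs)
  }
  out <- array(1, c(outSize, outSize, 3))
  idx <- which(inside)
  vals <- .bilinearSample(strip, vrow[idx], ucol[idx],
                          boundary = c("clamp", "wrap"))
  for (c in 1:3) {
    plane <- out[, , c]
    plane[idx] <- vals[, c]
    out[, , c] <- plane
  }
  out
}

#' Compose the probe stimulus from a ring image
#'
#' Resizes the ring to 120 x 120 pixels (bilinear) and centres it on a white
#' 160 x 120 canvas, the input geometry of the prediction network.
#'
#' @param ring square ring image.
#' @param canvasSize `c(height, width)` of the white canvas.
#' @param ringSize side of the resized ring.
#' @return `[120, 160, 3]` stimulus image.
#' @export
composeStimulus <- function(ring, canvasSize = c(120L, 160L),
                            ringSize = 120L) {
  .assertImage(ring)
  small <- resizeImage(ring, ringSize, ringSize)
  out <- array(1, c(canvasSize[1], canvasSize[2], 3))
  top <- (canvasSize[1] - ringSize) %/% 2L
  left <- (canvasSize[2] - ringSize) %/% 2L
  out[top + seq_len(ringSize), left + seq_len(ringSize), ] <- .clamp01(small)
  out
}

#' Build a circular illusion-like design from an image crop
#'
#' Crops a patch, optionally mirrors it left-right, tiles it `nS` times,
#' appends the white spacer of height [spacerHeight()], polar-warps the strip
#' into a ring and composes the 160 x 120 probe stimulus. The warp places the
#' patch mid-row exactly at radius `nS * x / (2 * pi)` (the unrounded
#' geometry), so the mapped arc length at the patch mid-line equals the strip
#' length.
#'
#' @param image source RGB image.
#' @param crop `c(left, top, width, height)` in 0-based pixels, half-open.
#' @param nS number of repetitions (default 20).
#' @param mirror build the left-right reversed variant.
#' @param outSize polar output side (default 1024).
#' @return a [RingDesign-class].
#' @export
makeRingDesign <- function(image, crop, nS = 20L, mirror = FALSE,
                           outSize = 1024L) {
  .assertImage(image)
  left <- crop[1]; top <- crop[2]; w <- crop[3]; hgt <- crop[4]
  d <- dim(image)
  if (left < 0 || top < 0 || left + w > d[2] || top + hgt > d[1])
    stop("crop is out of image bounds", call. = FALSE)
  patch <- image[top + seq_len(hgt), left + seq_len(w), , drop = FALSE]
  if (mirror) patch <- mirrorVariant(patch)
  h <- spacerHeight(w, hgt, nS)
  u <- (nS * w / pi - hgt) / 2          # unrounded spacer height
  strip <- addSpacer(tilePatch(patch, nS), h)
  ring <- polarRing(strip, outSize, innerRadius = u - h)
  spec <- new("RingSpec", x = as.integer(w), y = as.integer(hgt),
              nS = as.integer(nS), h = h, r = h + hgt / 2,
              outSize = as.integer(outSize))
  new("RingDesign", spec = spec, ring = ring,
      stimulus = composeStimulus(ring),
      variant = if (mirror) "reversed" else "original")
}

#' Rank candidate crop regions by local mean flow
#'
#' Helper for choosing the patch of a ring design: scores a crop window
#' centred at each flow start point by the mean magnitude of all vectors
#' whose start point falls inside the window. Exploratory — crop selection
#' for published designs was a manual step.
#'
#' @param flow a [FlowField-class].
#' @param cropWidth,cropHeight window size in pixels.
#' @return data.frame `left`, `top`, `width`, `height`, `meanFlow`, sorted
#'   by decreasing score.
#' @export
rankCrops <- function(flow, cropWidth = 9L, cropHeight = 26L) {
  v <- flowVectors(flow)
  if (!nrow(v)) return(data.frame(left = integer(0), top = integer(0),
                                  width = integer(0), height = integer(0),
                                  meanFlow = numeric(0)))
  H <- flow@imageDim[1]; W <- flow@imageDim[2]
  left <- pmin(pmax(round(v$start_x - cropWidth / 2), 0), W - cropWidth)
  top <- pmin(pmax(round(v$start_y - cropHeight / 2), 0), H - cropHeight)
  score <- vapply(seq_along(left), function(i) {
    inwin <- v$start_x >= left[i] & v$start_x < left[i] + cropWidth &
             v$start_y >= top[i] & v$start_y < top[i] + cropHeight
    mean(v$magnitude[inwin])
  }, 0)
  out <- unique(data.frame(left = left, top = top, width = cropWidth,
                           height = cropHeight, meanFlow = score))
  out <- out[order(-out$meanFlow), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @describeIn makeRingDesign the design's [RingSpec-class] as a list
#'   (suitable for JSON export).
#' @param design a [RingDesign-class].
#' @export
ringSpecAsList <- function(design) {
  s <- if (is(design, "RingDesign")) design@spec else design
  list(x = s@x, y = s@y, n_s = s@nS, h = s@h, r = s@r, out_size = s@outSize)
}

setMethod("show", "RingSpec", function(object) {
  cat(sprintf("RingSpec: patch %dx%d, %d repetitions, spacer h = %d, radius r = %.1f\n",
              object@x, object@y, object@nS, object@h, object@r))
})

setMethod("show", "RingDesign", function(object) {
  cat(sprintf("RingDesign (%s): ring %dx%d, stimulus %dx%d\n",
              object@variant, dim(object@ring)[1], dim(object@ring)[2],
              dim(object@stimulus)[1], dim(object@stimulus)[2]))
  show(object@spec)
})
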