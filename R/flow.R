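# Optical flow between two images: sparse (feature-based) and dense
# (stride-sampled) local least-squares estimation.
#
# Internals work on grayscale images scaled 0-255; flow vectors are in pixel
# units. Exported coordinates are 0-based.

.toFlowGray <- function(img) {
  g <- .luma(img)
  if (max(g) <= 1 + 1e-9) g <- g * 255
  g
}

.boxSum <- function(m, r) {
  # sum over a (2r+1)^2 window, replicate edges
  H <- nrow(m); W <- ncol(m)
  idx <- function(i, n) pmin(pmax(i, 1L), n)
  cs <- apply(m, 2, cumsum)
  rowSum <- cs[idx(seq_len(H) + r, H), , drop = FALSE] -
    rbind(matrix(0, min(r + 1, H), W),
          cs[seq_len(max(H - r - 1, 0)), , drop = FALSE])[seq_len(H), , drop = FALSE]
  cs2 <- t(apply(rowSum, 1, cumsum))
  cs2[, idx(seq_len(W) + r, W), drop = FALSE] -
    cbind(matrix(0, H, min(r + 1, W)),
          cs2[, seq_len(max(W - r - 1, 0)), drop = FALSE])[, seq_len(W), drop = FALSE]
}

#' Detect corner feature points (minimum-eigenvalue criterion)
#'
#' Computes the structure-tensor minimum-eigenvalue corner response over a
#' `blockSize` window, keeps 3x3 local maxima whose response is at least
#' `qualityLevel` times the global maximum, and returns at most `maxN`
#' points ordered by descending response (ties row-major).
#'
#' @param image RGB image or grayscale matrix.
#' @param qualityLevel relative response threshold in `(0, 1]`.
#' @param maxN maximum number of points returned.
#' @param blockSize odd side of the structure-tensor summation window.
#' @return data.frame with 0-based columns `x`, `y` and `response`; empty on
#'   featureless images.
#' @export
detectFeatures <- function(image, qualityLevel = 0.3, maxN = 100L,
                           blockSize = 3L) {
  stopifnot(qualityLevel > 0, qualityLevel <= 1)
  g <- .toFlowGray(image)
  gr <- .gradients(g)
  r <- (blockSize - 1L) %/% 2L
  Sxx <- .boxSum(gr$gx * gr$gx, r)
  Syy <- .boxSum(gr$gy * gr$gy, r)
  Sxy <- .boxSum(gr$gx * gr$gy, r)
  tr <- Sxx + Syy
  det2 <- sqrt(pmax((Sxx - Syy)^2 + 4 * Sxy^2, 0))
  resp <- (tr - det2) / 2
  H <- nrow(resp); W <- ncol(resp)
  border <- r + 1L
  resp[c(seq_len(border), H - seq_len(border) + 1L), ] <- 0
  resp[, c(seq_len(border), W - seq_len(border) + 1L)] <- 0
  mx <- max(resp)
  if (mx <= 0)
    return(data.frame(x = integer(0), y = integer(0), response = numeric(0)))
  # 3x3 non-maximum suppression (>= neighbours keeps plateau corners)
  shift <- function(m, dy, dx) {
    idx <- function(i, n) pmin(pmax(i, 1L), n)
    m[idx(seq_len(H) + dy, H), idx(seq_len(W) + dx, W), drop = FALSE]
  }
  isMax <- resp > 0 & resp >= qualityLevel * mx
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & (resp >= shift(resp, dy, dx))
  }
  pts <- which(isMax, arr.ind = TRUE)
  if (!nrow(pts))
    return(data.frame(x = integer(0), y = integer(0), response = numeric(0)))
  out <- data.frame(x = pts[, 2] - 1L, y = pts[, 1] - 1L,
                    response = resp[pts])
  out <- out[order(-out$response, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  head(out, maxN)
}

# Iterative pyramidal Lucas-Kanade at the given 0-based points, vectorised
# across points. Returns a data.frame start_x, start_y, dx, dy, valid.
.lkFlow <- function(grayA, grayB, pts, windowSize, levels = 2L,
                    maxIter = 15L, eps = 1e-3, minEig = 1e-4,
                    requireInside = FALSE) {
  pyrA <- list(grayA); pyrB <- list(grayB)
  if (levels > 1L) for (l in 2:levels) {
    pyrA[[l]] <- .downsample2(.gaussBlur(pyrA[[l - 1L]], 1))
    pyrB[[l]] <- .downsample2(.gaussBlur(pyrB[[l - 1L]], 1))
  }
  grads <- lapply(pyrA, .gradients)
  off <- seq_len(windowSize) - (windowSize + 1) / 2
  offY <- rep(off, times = windowSize)
  offX <- rep(off, each = windowSize)
  W2 <- windowSize^2

  n <- nrow(pts)
  d <- matrix(0, n, 2)
  valid <- rep(TRUE, n)
  if (requireInside) {
    hw <- (windowSize - 1) / 2
    valid <- pts$x + 1 - hw >= 1 & pts$x + 1 + hw <= ncol(grayA) &
             pts$y + 1 - hw >= 1 & pts$y + 1 + hw <= nrow(grayA)
  }
  for (l in levels:1) {
    sc <- 2^(l - 1L)
    px <- (pts$x + 1) / sc      # 1-based fractional centres at this level
    py <- (pts$y + 1) / sc
    wy <- rep(py, each = W2) + rep(offY, times = n)
    wx <- rep(px, each = W2) + rep(offX, times = n)
    Aw <- .bilinearSample(pyrA[[l]], wy, wx, "clamp")
    IxM <- matrix(.bilinearSample(grads[[l]]$gx, wy, wx, "clamp"), W2, n)
    IyM <- matrix(.bilinearSample(grads[[l]]$gy, wy, wx, "clamp"), W2, n)
    Gxx <- colSums(IxM * IxM); Gxy <- colSums(IxM * IyM)
    Gyy <- colSums(IyM * IyM)
    eig <- ((Gxx + Gyy) - sqrt((Gxx - Gyy)^2 + 4 * Gxy^2)) / 2
    valid <- valid & eig / W2 >= minEig
    det <- Gxx * Gyy - Gxy * Gxy
    det[!valid | det <= 0] <- 1          # masked out below
    for (it in seq_len(maxIter)) {
      Bw <- .bilinearSample(pyrB[[l]], wy + rep(d[, 2], each = W2),
                            wx + rep(d[, 1], each = W2), "clamp")
      It <- matrix(Bw - Aw, W2, n)
      b1 <- -colSums(IxM * It); b2 <- -colSums(IyM * It)
      sx <- (Gyy * b1 - Gxy * b2) / det
      sy <- (Gxx * b2 - Gxy * b1) / det
      sx[!valid] <- 0; sy[!valid] <- 0
      d[, 1] <- d[, 1] + sx
      d[, 2] <- d[, 2] + sy
      if (max(abs(c(sx, sy))) < eps) break
    }
    if (l > 1L) d <- d * 2
  }
  # a local constant-flow solution larger than its own integration window is
  # a divergent iteration, not a measurement
  valid <- valid & sqrt(d[, 1]^2 + d[, 2]^2) <= windowSize
  data.frame(start_x = pts$x, start_y = pts$y, dx = d[, 1], dy = d[, 2],
             valid = valid & is.finite(d[, 1]) & is.finite(d[, 2]))
}

.flowField <- function(df, method, imgDim) {
  new("FlowField", vectors = df[, c("start_x", "start_y", "dx", "dy")],
      method = method, imageDim = as.integer(imgDim))
}

#' Sparse optical flow at feature points
#'
#' Pyramidal iterative Lucas–Kanade: each point's displacement solves the
#' local constant-flow least-squares problem over a square integration window
#' of side `windowSize`, refined across `levels` pyramid levels. Two
#' documented validity checks drop points silently: a near-singular normal
#' matrix (normalised minimum eigenvalue below `minEig`) and an integration
#' window that is not fully contained in the image at full resolution.
#'
#' @param imgA,imgB images of equal size (RGB arrays or grayscale matrices);
#'   flow is estimated from A to B.
#' @param points data.frame with 0-based `x`, `y` start points (e.g. from
#'   [detectFeatures()]); defaults to detecting features on `imgA`.
#' @param windowSize side of the integration window in pixels (default 50).
#' @param levels pyramid levels (default 2).
#' @param minEig validity floor for the per-pixel-normalised minimum
#'   eigenvalue of the normal matrix.
#' @return a [FlowField-class] with method `"sparse"`.
#' @export
sparseFlow <- function(imgA, imgB, points = NULL, windowSize = 50L,
                       levels = 2L, minEig = 1e-4) {
  gA <- .toFlowGray(imgA); gB <- .toFlowGray(imgB)
  if (!identical(dim(gA), dim(gB)))
    stop("images must have identical dimensions", call. = FALSE)
  if (is.null(points)) points <- detectFeatures(imgA)
  if (nrow(points) == 0L)
    return(.flowField(data.frame(start_x = numeric(0), start_y = numeric(0),
                                 dx = numeric(0), dy = numeric(0)),
                      "sparse", dim(gA)))
  if (any(points$x < 0 | points$x > ncol(gA) - 1 |
          points$y < 0 | points$y > nrow(gA) - 1))
    stop("feature points must lie within the image", call. = FALSE)
  res <- .lkFlow(gA, gB, points, windowSize, levels, minEig = minEig,
                 requireInside = TRUE)
  .flowField(res[res$valid, , drop = FALSE], "sparse", dim(gA))
}

#' Dense optical flow on a stride grid
#'
#' Estimates flow by local least squares (window `windowSize`) at every
#' `stride`-th pixel in x and y, then discards vectors with magnitude below
#' `minVec`. Each grid point's estimate depends only on its own window, so
#' this equals computing the full dense field and sampling it on the grid.
#' Near-singular windows and divergent solutions (displacement beyond the
#' window size) are dropped.
#'
#' @inheritParams sparseFlow
#' @param windowSize averaging window side in pixels (default 10).
#' @param stride grid spacing in pixels (default 5).
#' @param minVec minimum retained vector magnitude (default 0.01).
#' @return a [FlowField-class] with method `"dense"`.
#' @export
denseFlow <- function(imgA, imgB, windowSize = 10L, stride = 5L,
                      minVec = 0.01, levels = 2L, minEig = 1e-4) {
  gA <- .toFlowGray(imgA); gB <- .toFlowGray(imgB)
  if (!identical(dim(gA), dim(gB)))
    stop("images must have identical dimensions", call. = FALSE)
  stopifnot(stride >= 1, minVec >= 0)
  xs <- seq(0L, ncol(gA) - 1L, by = stride)
  ys <- seq(0L, nrow(gA) - 1L, by = stride)
  pts <- expand.grid(x = xs, y = ys)
  res <- .lkFlow(gA, gB, pts, windowSize, levels, minEig = minEig)
  res <- res[res$valid & sqrt(res$dx^2 + res$dy^2) >= minVec, , drop = FALSE]
  rownames(res) <- NULL
  .flowField(res, "dense", dim(gA))
}

#' @describeIn sparseFlow accessor for the vector table (with magnitudes).
#' @param flow a [FlowField-class].
#' @export
flowVectors <- function(flow) {
  v <- flow@vectors
  v$magnitude <- sqrt(v$dx^2 + v$dy^2)
  v$method <- rep(flow@method, nrow(v))
  v
}

#' Write / read a flow field as CSV
#'
#' Columns: `start_x`, `start_y`, `dx`, `dy`, `magnitude`, `method`
#' (header mandatory).
#'
#' @param flow a [FlowField-class].
#' @param path CSV file path.
#' @param imageDim `c(height, width)` of the source image, used when reading.
#' @return `readFlowCSV` returns a [FlowField-class]; `writeFlowCSV` returns
#'   `path` invisibly.
#' @export
writeFlowCSV <- function(flow, path) {
  write.csv(flowVectors(flow), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFlowCSV
#' @export
readFlowCSV <- function(path, imageDim) {
  df <- read.csv(path)
  method <- if (nrow(df)) df$method[1] else "sparse"
  .flowField(df[, c("start_x", "start_y", "dx", "dy"), drop = FALSE],
             method, imageDim)
}

#' Render flow vectors over an image
#'
#' Draws yellow start points and red lines whose length is `scale` times the
#' vector magnitude (defaults: 50 for sparse, 4 for dense fields).
#'
#' @param image background RGB image.
#' @param flow a [FlowField-class].
#' @param scale line-length multiplier; `NULL` picks the method default.
#' @param path optional PNG output path.
#' @return the overlay image array, invisibly if `path` is given.
#' @export
renderFlowOverlay <- function(image, flow, scale = NULL, path = NULL) {
  .assertImage(image)
  if (is.null(scale)) scale <- if (flow@method == "sparse") 50 else 4
  out <- image
  H <- dim(out)[1]; W <- dim(out)[2]
  put <- function(out, ys, xs, col) {
    keep <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    ys <- ys[keep]; xs <- xs[keep]
    for (c in 1:3) out[cbind(ys, xs, c)] <- col[c]
    out
  }
  v <- flow@vectors
  for (i in seq_len(nrow(v))) {
    x0 <- v$start_x[i] + 1; y0 <- v$start_y[i] + 1
    x1 <- x0 + scale * v$dx[i]; y1 <- y0 + scale * v$dy[i]
    npts <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) + 1L)
    tt <- seq(0, 1, length.out = npts)
    out <- put(out, round(y0 + tt * (y1 - y0)), round(x0 + tt * (x1 - x0)),
               c(1, 0, 0))
  }
  out <- put(out, round(v$start_y + 1), round(v$start_x + 1), c(1, 1, 0))
  if (!is.null(path)) {
    writeImageRGB(out, path)
    return(invisible(out))
  }
  out
}

setMethod("show", "FlowField", function(object) {
  cat(sprintf("FlowField (%s): %d vector(s) on a %dx%d image\n",
              object@method, nrow(object@vectors),
              object@imageDim[1], object@imageDim[2]))
})
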