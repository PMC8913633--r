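# Static-image probing protocol and brightness line-profile analysis.

#' Predict the P1 and P2 frames for a static probe image
#'
#' Runs the probing protocol: from a fresh recurrent state, 21 copies of the
#' probe image are fed to the network and the prediction issued after the
#' 21st frame is the P1 image (the predicted 22nd frame); P1 is then fed back
#' as the 22nd input, and the following prediction is the P2 image (the
#' predicted 23rd frame). The rollout is continuous — the state is not reset
#' between P1 and P2 — and the result is deterministic per model.
#'
#' @param model a [PredNetModel-class].
#' @param probe probe image, `[H, W, 3]` array in `[0, 1]` matching the
#'   model's input shape.
#' @param nContext number of probe copies fed before P1 (default 21).
#' @return a [PredictionPair-class].
#' @export
predictPair <- function(model, probe, nContext = 21L) {
  stopifnot(is(model, "PredNetModel"))
  .checkFrame(model@config, probe)
  st <- initState(model@config)
  pred <- NULL
  for (t in seq_len(nContext)) {
    r <- .fwdStep(model@config, model@weights, st, probe)
    st <- r$state; pred <- r$prediction
  }
  p1 <- pred
  r <- .fwdStep(model@config, model@weights, st, p1)
  new("PredictionPair", p1 = p1, p2 = r$prediction, probe = probe)
}

#' Convert an RGB image to 8-bit grayscale brightness
#'
#' Uses the standard luma weighting `0.299 R + 0.587 G + 0.114 B` and returns
#' brightness on the 0–255 scale, rounded to integers (so a pure gray
#' `(g, g, g)` maps to `g`).
#'
#' @param image `[H, W, 3]` array in `[0, 1]` (or values already in 0–255,
#'   detected by range).
#' @return integer-valued `[H, W]` matrix in 0–255.
#' @export
toGrayscale <- function(image) {
  .assertImage(image)
  scale <- if (max(image) > 1 + 1e-9) 1 else 255
  round(.luma(image) * scale)
}

#' Extract a brightness profile along a row or column segment
#'
#' The line is given in 0-based pixel coordinates with an end-exclusive
#' range, e.g. `list(row = 60, cols = c(10, 50))` for a horizontal segment
#' or `list(col = 80, rows = c(0, 120))` for a vertical one.
#'
#' @param image RGB image or grayscale matrix.
#' @param line a list as above.
#' @return object of class `LineProfile`: list with `values` (brightness,
#'   0–255) and `line`.
#' @export
extractProfile <- function(image, line) {
  gray <- if (is.matrix(image)) image else toGrayscale(image)
  H <- nrow(gray); W <- ncol(gray)
  row <- line[["row"]]; cols <- line[["cols"]]
  col <- line[["col"]]; rows <- line[["rows"]]
  if (!is.null(row)) {
    if (row < 0 || row > H - 1 ||
        cols[1] < 0 || cols[2] > W || cols[1] >= cols[2])
      stop("line is out of image bounds", call. = FALSE)
    vals <- gray[row + 1L, (cols[1] + 1L):cols[2]]
  } else if (!is.null(col)) {
    if (col < 0 || col > W - 1 ||
        rows[1] < 0 || rows[2] > H || rows[1] >= rows[2])
      stop("line is out of image bounds", call. = FALSE)
    vals <- gray[(rows[1] + 1L):rows[2], col + 1L]
  } else {
    stop("line must contain either 'row' and 'cols' or 'col' and 'rows'",
         call. = FALSE)
  }
  structure(list(values = as.numeric(vals), line = line),
            class = "LineProfile")
}

#' Signed displacement between two brightness profiles
#'
#' Returns the integer lag maximizing the normalized cross-correlation of the
#' two profiles over their overlapping region. A positive value means
#' `profileB` is displaced toward increasing coordinate relative to
#' `profileA` (i.e. `profileB[i + shift]` matches `profileA[i]`). Lags up to
#' half the profile length are searched; ties are broken toward the smallest
#' absolute lag, then toward the positive lag.
#'
#' @param profileA,profileB `LineProfile` objects or numeric vectors of equal
#'   length (at least 8).
#' @return signed integer shift in pixels.
#' @export
profileShift <- function(profileA, profileB) {
  a <- if (inherits(profileA, "LineProfile")) profileA$values else as.numeric(profileA)
  b <- if (inherits(profileB, "LineProfile")) profileB$values else as.numeric(profileB)
  n <- length(a)
  if (length(b) != n) stop("profiles must have equal length", call. = FALSE)
  if (n < 8L) stop("profiles must have length >= 8", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("shift is undefined for constant (zero-variance) profiles",
         call. = FALSE)
  maxLag <- n %/% 2L
  lags <- seq(-maxLag, maxLag)
  cors <- vapply(lags, function(s) {
    if (s >= 0) { ia <- seq_len(n - s); ib <- ia + s }
    else        { ib <- seq_len(n + s); ia <- ib - s }
    x <- a[ia]; y <- b[ib]
    if (sd(x) == 0 || sd(y) == 0) return(-Inf)
    suppressWarnings(stats::cor(x, y))
  }, 0)
  cors[!is.finite(cors)] <- -Inf
  best <- max(cors)
  cand <- lags[cors >= best - 1e-12]
  cand[order(abs(cand), -cand)][1]
}
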