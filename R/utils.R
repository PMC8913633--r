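# Internal array and image utilities. Convention: images are [H, W, C] arrays
# (or [H, W] matrices for grayscale) in [0, 1]; exported pixel coordinates are
# 0-based (x = column, y = row).

.zeros <- function(...) array(0, dim = c(...))

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

.isImage <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

.assertImage <- function(x, what = "image") {
  if (!.isImage(x))
    stop(what, " must be a numeric [height, width, 3] array", call. = FALSE)
  invisible(x)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

# ITU-R BT.601 luma weights (the convention used by common image libraries'
# RGB-to-gray conversion). Returns [H, W] in the same scale as the input.
.luma <- function(img) {
  if (is.matrix(img)) return(img)
  .assertImage(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Bilinear sampling of a [H, W] matrix or [H, W, C] array at fractional
# 1-based coordinates (ys, xs), vectors of equal length. `boundary` controls
# out-of-range handling: "clamp", "reflect", "wrap", or "constant" (fill);
# a length-2 value gives separate modes for the y and x axes.
.bilinearSample <- function(img, ys, xs, boundary = "clamp", fill = 1) {
  isMat <- is.matrix(img)
  d <- dim(img)
  H <- d[1]; W <- d[2]; C <- if (isMat) 1L else d[3]
  bnd <- rep(boundary, length.out = 2L)

  mapIdx <- function(v, n, mode) {
    if (identical(mode, "wrap")) {
      ((v - 1) %% n) + 1
    } else if (identical(mode, "reflect")) {
      # reflect about the edge pixels: 0 -> 2, n+1 -> n-1
      p <- (v - 1) %% (2 * n - 2)
      ifelse(p > n - 1, 2 * n - 2 - p, p) + 1
    } else {
      pmin(pmax(v, 1), n)
    }
  }

  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0;   fx <- xs - x0
  out <- matrix(0, length(ys), C)
  outside <- (if (bnd[1] == "constant") ys < 1 | ys > H else FALSE) |
             (if (bnd[2] == "constant") xs < 1 | xs > W else FALSE)
  i00 <- cbind(mapIdx(y0, H, bnd[1]),     mapIdx(x0, W, bnd[2]))
  i10 <- cbind(mapIdx(y0 + 1, H, bnd[1]), mapIdx(x0, W, bnd[2]))
  i01 <- cbind(mapIdx(y0, H, bnd[1]),     mapIdx(x0 + 1, W, bnd[2]))
  i11 <- cbind(mapIdx(y0 + 1, H, bnd[1]), mapIdx(x0 + 1, W, bnd[2]))
  for (c in seq_len(C)) {
    pl <- if (isMat) img else img[, , c]
    v <- (1 - fy) * (1 - fx) * pl[i00] + fy * (1 - fx) * pl[i10] +
         (1 - fy) * fx * pl[i01] + fy * fx * pl[i11]
    if (any(bnd == "constant")) v[outside] <- fill
    out[, c] <- v
  }
  if (isMat) out[, 1] else out
}

# Resample img ([H,W] or [H,W,C]) onto a full grid of fractional coordinates
# given as matrices YS, XS of the output size.
.warpImage <- function(img, YS, XS, boundary = "clamp", fill = 1) {
  isMat <- is.matrix(img)
  v <- .bilinearSample(img, as.vector(YS), as.vector(XS), boundary, fill)
  if (isMat) {
    matrix(v, nrow(YS), ncol(YS))
  } else {
    array(v, c(nrow(YS), ncol(YS), dim(img)[3]))
  }
}

# Translate an image by (dx, dy) pixels (content moves right/down for
# positive values) with the given boundary rule.
.translateImage <- function(img, dx, dy, boundary = "reflect") {
  d <- dim(img); H <- d[1]; W <- d[2]
  YS <- matrix(seq_len(H), H, W) - dy
  XS <- matrix(seq_len(W), H, W, byrow = TRUE) - dx
  .warpImage(img, YS, XS, boundary)
}

# Separable Gaussian blur of a matrix with "replicate" edges.
.gaussBlur <- function(m, sigma, wrap = FALSE) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(x, n, side) {
    if (wrap) {
      if (side == "pre") x[(nrow(x) - n + 1):nrow(x), , drop = FALSE]
      else x[1:n, , drop = FALSE]
    } else {
      if (side == "pre") x[rep(1L, n), , drop = FALSE]
      else x[rep(nrow(x), n), , drop = FALSE]
    }
  }
  smoothDim <- function(x) {          # filter along rows
    xp <- rbind(pad(x, r, "pre"), x, pad(x, r, "post"))
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[(i - 1) + seq_len(nrow(x)), , drop = FALSE]
    out
  }
  t(smoothDim(t(smoothDim(m))))
}

# Grayscale [0,1] matrix -> x/y intensity gradients (central differences,
# replicated edges), each the same size as the input.
.gradients <- function(m) {
  H <- nrow(m); W <- ncol(m)
  gx <- (m[, c(2:W, W)] - m[, c(1, 1:(W - 1))]) / 2
  gy <- (m[c(2:H, H), ] - m[c(1, 1:(H - 1)), ]) / 2
  list(gx = gx, gy = gy)
}

.downsample2 <- function(m) {
  H <- nrow(m) - nrow(m) %% 2L; W <- ncol(m) - ncol(m) %% 2L
  m <- m[seq_len(H), seq_len(W), drop = FALSE]
  (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
   m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)]) / 4
}
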