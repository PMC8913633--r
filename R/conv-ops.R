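# Internal convolution primitives for the predictive-coding network.
#
# Tensors are [H, W, C] arrays. A convolution weight is stored as a
# (k*k*Cin) x Cout matrix whose rows are ordered by kernel offset
# (dy major, dx minor, both 0..k-1) and then input channel, matching the
# im2col column layout:
#
#   out[y, x, co] = b[co] +
#     sum_{dy, dx, ci} xpad[y + dy, x + dx, ci] * W[(dy*k + dx)*Cin + ci, co]
#
# with xpad the input zero-padded by p = (k - 1) / 2 ("same" convolution,
# cross-correlation orientation). k must be odd.

.im2col <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  if (k == 1L) return(matrix(x, H * W, C))
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2 * p, W + 2 * p, C))
  xp[p + seq_len(H), p + seq_len(W), ] <- x
  cols <- matrix(0, H * W, k * k * C)
  j <- 0L
  for (dy in 0:(k - 1)) {
    for (dx in 0:(k - 1)) {
      cols[, j * C + seq_len(C)] <-
        matrix(xp[dy + seq_len(H), dx + seq_len(W), , drop = FALSE], H * W, C)
      j <- j + 1L
    }
  }
  cols
}

.col2im <- function(dcols, H, W, C, k) {
  if (k == 1L) return(array(dcols, c(H, W, C)))
  p <- (k - 1L) %/% 2L
  dxp <- array(0, c(H + 2 * p, W + 2 * p, C))
  j <- 0L
  for (dy in 0:(k - 1)) {
    for (dx in 0:(k - 1)) {
      dxp[dy + seq_len(H), dx + seq_len(W), ] <-
        dxp[dy + seq_len(H), dx + seq_len(W), , drop = FALSE] +
        array(dcols[, j * C + seq_len(C)], c(H, W, C))
      j <- j + 1L
    }
  }
  dxp[p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

.conv2d <- function(x, W, b, k) {
  d <- dim(x)
  cols <- .im2col(x, k)
  out <- cols %*% W
  out <- out + rep(b, each = nrow(out))
  array(out, c(d[1], d[2], length(b)))
}

# Backward pass of .conv2d. dout: [H, W, Cout]; x: the forward input.
# Returns gradients dW, db, dx.
.conv2dBack <- function(dout, x, W, k) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]
  dm <- matrix(dout, H * Wd, dim(dout)[3])
  cols <- .im2col(x, k)
  list(dW = crossprod(cols, dm),
       db = colSums(dm),
       dx = .col2im(dm %*% t(W), H, Wd, C, k))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.maxpool2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  a  <- x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE]
  b  <- x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE]
  cc <- x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE]
  dd <- x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  idx <- array(4L, dim(out))
  idx[out == cc] <- 3L
  idx[out == b]  <- 2L
  idx[out == a]  <- 1L     # ties resolved toward the top-left corner
  list(out = out, idx = idx)
}

.maxpool2Back <- function(dout, idx, H, W) {
  dx <- array(0, c(H, W, dim(dout)[3]))
  dx[seq(1, H, 2), seq(1, W, 2), ] <- dout * (idx == 1L)
  dx[seq(2, H, 2), seq(1, W, 2), ] <- dout * (idx == 2L)
  dx[seq(1, H, 2), seq(2, W, 2), ] <- dout * (idx == 3L)
  dx[seq(2, H, 2), seq(2, W, 2), ] <- dout * (idx == 4L)
  dx
}

.upsample2 <- function(x) {
  x[rep(seq_len(dim(x)[1]), each = 2), rep(seq_len(dim(x)[2]), each = 2), ,
    drop = FALSE]
}

.upsample2Back <- function(d) {
  H2 <- dim(d)[1]; W2 <- dim(d)[2]
  d[seq(1, H2, 2), seq(1, W2, 2), , drop = FALSE] +
    d[seq(2, H2, 2), seq(1, W2, 2), , drop = FALSE] +
    d[seq(1, H2, 2), seq(2, W2, 2), , drop = FALSE] +
    d[seq(2, H2, 2), seq(2, W2, 2), , drop = FALSE]
}
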