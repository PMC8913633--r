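# Synthetic inputs for the pipeline: training videos with coherent global
# motion (a desk-scale stand-in for first-person footage), illusion-style
# images built from repeated asymmetric luminance-gradient units, matched
# control images, and ground-truth flow fixtures. Every generator is
# deterministic under a fixed seed.

# Smooth periodic (toroidal) texture in [lo, hi]; wrap-around blur makes
# translation with wrap boundary artefact-free.
.smoothTexture <- function(H, W, sigma = 3, lo = 0.05, hi = 0.95) {
  m <- .gaussBlur(matrix(runif(H * W), H, W), sigma, wrap = TRUE)
  rng <- range(m)
  if (diff(rng) < 1e-12) return(matrix((lo + hi) / 2, H, W))
  lo + (m - rng[1]) / diff(rng) * (hi - lo)
}

.colorize <- function(gray, tint = c(1, 1, 1)) {
  array(c(gray * tint[1], gray * tint[2], gray * tint[3]),
        c(nrow(gray), ncol(gray), 3))
}

.sceneImage <- function(H, W) {
  # simple rendered scene: sky gradient plus a few rectangles
  img <- .colorize(matrix(rep(seq(0.9, 0.5, length.out = H), W), H, W),
                   c(0.85, 0.9, 1))
  nRect <- sample(3:6, 1)
  lo <- max(3L, min(H, W) %/% 8L); hi <- max(lo + 1L, min(H, W) %/% 3L)
  for (i in seq_len(nRect)) {
    w <- sample(lo:hi, 1); h <- sample(lo:hi, 1)
    x0 <- sample(seq_len(W - w), 1); y0 <- sample(seq_len(H - h), 1)
    col <- runif(3, 0.1, 0.8)
    for (c in 1:3) img[y0 + seq_len(h) - 1, x0 + seq_len(w) - 1, c] <- col[c]
  }
  img
}

#' Generate a synthetic training video
#'
#' Emulates, at desk scale, video with coherent global motion of the kind a
#' head-mounted camera records:
#' * `"drifting_texture"`: a smooth toroidal texture translating at
#'   `velocity` px/frame.
#' * `"translating_scene"`: a rendered scene (gradient + rectangles)
#'   translating at `velocity` px/frame, with per-frame ground-truth
#'   displacement returned.
#' * `"static_segments"`: a new random texture every `segmentLength` frames,
#'   constant within each segment.
#' * `"mixed"`: alternating drifting (random direction, speed `|velocity|`)
#'   and static segments.
#'
#' @param kind one of the four kinds above.
#' @param nFrames number of frames.
#' @param frameSize `c(height, width)` (default 120 x 160).
#' @param velocity `c(dx, dy)` in px/frame.
#' @param segmentLength frames per segment for the segmented kinds.
#' @param seed integer seed; the output is bit-identical per seed.
#' @return list with `frames` (list of `[H, W, 3]` arrays in `[0, 1]`),
#'   `truth` (data.frame `frame`, `dx`, `dy` of the displacement from the
#'   previous frame) and `kind`.
#' @export
makeTrainingVideo <- function(kind = c("drifting_texture", "translating_scene",
                                       "static_segments", "mixed"),
                              nFrames = 100L, frameSize = c(120L, 160L),
                              velocity = c(1, 0), segmentLength = 10L,
                              seed = 1L) {
  kind <- match.arg(kind)
  H <- frameSize[1]; W <- frameSize[2]
  .withSeed(seed, {
    frames <- vector("list", nFrames)
    dx <- numeric(nFrames); dy <- numeric(nFrames)
    if (kind %in% c("drifting_texture", "translating_scene")) {
      base <- if (kind == "drifting_texture") {
        tint <- runif(3, 0.85, 1)
        .colorize(.smoothTexture(H, W), tint)
      } else .sceneImage(H, W)
      for (t in seq_len(nFrames)) {
        sh <- (t - 1) * velocity
        frames[[t]] <- .clamp01(.translateImage(base, sh[1], sh[2], "wrap"))
        if (t > 1) { dx[t] <- velocity[1]; dy[t] <- velocity[2] }
      }
    } else if (kind == "static_segments") {
      t <- 1L
      while (t <= nFrames) {
        seg <- .colorize(.smoothTexture(H, W), runif(3, 0.85, 1))
        for (i in seq_len(min(segmentLength, nFrames - t + 1L))) {
          frames[[t]] <- seg
          t <- t + 1L
        }
      }
    } else { # mixed
      speed <- max(sqrt(sum(velocity^2)), 1)
      dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
      t <- 1L; segIdx <- 0L
      while (t <= nFrames) {
        segIdx <- segIdx + 1L
        base <- .colorize(.smoothTexture(H, W), runif(3, 0.85, 1))
        moving <- segIdx %% 2L == 1L
        v <- if (moving) speed * dirs[[sample.int(4, 1)]] else c(0, 0)
        for (i in seq_len(min(segmentLength, nFrames - t + 1L))) {
          sh <- (i - 1) * v
          frames[[t]] <- .clamp01(.translateImage(base, sh[1], sh[2], "wrap"))
          if (i > 1) { dx[t] <- v[1]; dy[t] <- v[2] }
          t <- t + 1L
        }
      }
    }
    list(frames = frames,
         truth = data.frame(frame = seq_len(nFrames), dx = dx, dy = dy),
         kind = kind)
  })
}

#' Generate a synthetic illusion-style image
#'
#' Concentric rings whose angular luminance profile is a repeating
#' asymmetric (sawtooth) light-to-dark gradient — the repeated-unit
#' structure characteristic of peripheral-drift-type motion illusions —
#' with `nReps` units per revolution. The sawtooth direction alternates
#' between adjacent radial bands. A symmetric (`"triangle"`) unit profile
#' is available as a non-directional control.
#'
#' @param nReps number of gradient units per revolution (>= 2).
#' @param unit `"sawtooth"` (asymmetric) or `"triangle"` (symmetric).
#' @param size `c(height, width)` of the output (default 120 x 160).
#' @param bandWidth radial band width in pixels.
#' @param seed seed for the random phase.
#' @return `[H, W, 3]` array in `[0, 1]`; background is white.
#' @export
makeIllusionImage <- function(nReps = 12L, unit = c("sawtooth", "triangle"),
                              size = c(120L, 160L), bandWidth = 11L,
                              seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(nReps >= 2L)
  H <- size[1]; W <- size[2]
  .withSeed(seed, {
    phase0 <- runif(1)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    rOut <- min(H, W) / 2 - 4
    rIn <- max(6, rOut / 5)
    xs <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
    ys <- matrix(seq_len(H), H, W) - cy
    rho <- sqrt(xs^2 + ys^2)
    theta <- atan2(-ys, xs) %% (2 * pi)
    band <- floor((rho - rIn) / bandWidth)
    dirn <- 1 - 2 * (band %% 2)          # alternate per band
    ph <- (nReps * theta / (2 * pi) + phase0) * dirn
    lum <- ph %% 1
    if (unit == "triangle") lum <- 1 - 2 * abs(lum - 0.5)
    lum <- 0.08 + 0.87 * lum
    inside <- rho >= rIn & rho <= rOut
    gray <- matrix(1, H, W)
    gray[inside] <- lum[inside]
    img <- .colorize(gray, c(1, 1, 1))
    img[, , 3] <- img[, , 3] * 0.9 + 0.1  # mild warm/cool separation
    .clamp01(img)
  })
}

#' Generate a matched control image
#'
#' * `"texture"`: a phase-randomized version of the paired illusion image —
#'   the Fourier amplitude spectrum (hence the global luminance histogram's
#'   mean and contrast) is preserved while all spatial structure, including
#'   periodic angular structure, is destroyed.
#' * `"scene"`: a simple rendered scene (gradient + rectangles), shifted to
#'   match the paired image's mean luminance.
#'
#' @param paired the illusion image to match (`[H, W, 3]`).
#' @param type `"texture"` or `"scene"`.
#' @param seed integer seed.
#' @return `[H, W, 3]` array in `[0, 1]` with mean luminance within 2/255 of
#'   the paired image.
#' @export
makeControlImage <- function(paired, type = c("texture", "scene"), seed = 1L) {
  type <- match.arg(type)
  .assertImage(paired)
  H <- dim(paired)[1]; W <- dim(paired)[2]
  target <- mean(.luma(paired))
  .withSeed(seed, {
    if (type == "texture") {
      g <- .luma(paired)
      Fa <- fft(g)
      phase <- Arg(fft(matrix(runif(H * W), H, W)))
      Fr <- Mod(Fa) * exp(1i * phase)
      Fr[1, 1] <- Fa[1, 1]               # keep the DC term: mean preserved
      g2 <- .clamp01(Re(fft(Fr, inverse = TRUE)) / (H * W))
      for (it in 1:8) g2 <- .clamp01(g2 + (target - mean(g2)))
      img <- .colorize(g2, c(1, 1, 1))
    } else {
      img <- .sceneImage(H, W)
      for (it in 1:8) img <- .clamp01(img + (target - mean(.luma(img))))
    }
    img
  })
}

#' Generate labelled synthetic test groups with a manifest
#'
#' Builds `nPerGroup` images for each of the groups `illusion`,
#' `control_texture` and `control_scene`, writes them as PNG files plus a
#' tab-separated manifest (`image_path`, `group_label`), and returns the
#' manifest with the images attached.
#'
#' @param nPerGroup images per group.
#' @param dir output directory (created if needed).
#' @param seed integer seed; output files are identical per seed.
#' @return invisibly, a list with `manifest` (data.frame) and `images`
#'   (named list of arrays).
#' @export
makeTestGroups <- function(nPerGroup = 10L, dir = tempfile("groups"),
                           seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- c("illusion", "control_texture", "control_scene")
  rows <- list(); images <- list()
  for (i in seq_len(nPerGroup)) {
    s <- seed * 1000L + i
    ill <- makeIllusionImage(nReps = 8L + 2L * (i %% 5L), seed = s)
    imgs <- list(illusion = ill,
                 control_texture = makeControlImage(ill, "texture", seed = s),
                 control_scene = makeControlImage(ill, "scene", seed = s))
    for (g in groups) {
      fn <- file.path(dir, sprintf("%s_%02d.png", g, i))
      writeImageRGB(imgs[[g]], fn)
      rows[[length(rows) + 1L]] <- data.frame(image_path = fn, group_label = g)
      images[[basename(fn)]] <- imgs[[g]]
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, images = images, dir = dir))
}

#' Build a ground-truth optical-flow fixture
#'
#' Warps `image` by `(dx, dy)` pixels (bilinear, reflected boundary) so the
#' true displacement of every pixel is known.
#'
#' @param image source image.
#' @param dx,dy displacement in pixels (may be fractional).
#' @return list with `a` (original), `b` (warped) and `truth = c(dx, dy)`.
#' @export
makeFlowFixture <- function(image, dx, dy) {
  list(a = image, b = .translateImage(image, dx, dy, "reflect"),
       truth = c(dx = dx, dy = dy))
}

#' A smooth random texture image (exported fixture helper)
#'
#' @param size `c(height, width)`.
#' @param sigma blur scale of the texture in pixels.
#' @param seed integer seed.
#' @return `[H, W, 3]` array in `[0, 1]`.
#' @export
makeTextureImage <- function(size = c(120L, 160L), sigma = 2, seed = 1L) {
  .withSeed(seed, .colorize(.smoothTexture(size[1], size[2], sigma), c(1, 1, 1)))
}
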