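# Ring-design geometry: spacer equation, tiling, polar warp, mirroring,
# stimulus composition.

test_that("spacerHeight implements the circumference equation with floor", {
  expect_identical(spacerHeight(9, 26, 20), 15L)
  expect_identical(spacerHeight(8, 18, 20), 16L)
  expect_identical(spacerHeight(10, 20, 20), 21L)  # floor(21.83)
  expect_error(spacerHeight(2, 40, 3), "too tall")
})

test_that("the floored spacer keeps the circumference within one floor error", {
  for (case in list(c(9, 26), c(8, 18), c(10, 20), c(5, 7), c(12, 40))) {
    h <- spacerHeight(case[1], case[2], 20)
    expect_lt(abs(20 * case[1] - 2 * pi * (h + case[2] / 2)), 2 * pi)
  }
})

test_that("tilePatch repeats the patch periodically", {
  patch <- makeTextureImage(c(26, 9), seed = 3)
  strip <- tilePatch(patch, 20)
  expect_identical(dim(strip), c(26L, 180L, 3L))
  expect_identical(tilePatch(patch, 1), patch)
  expect_identical(strip[, 1, ], strip[, 10, ])   # columns 0 and x identical
  expect_identical(strip[, 5, ], strip[, 5 + 9 * 7, ])
})

test_that("addSpacer appends a full-width pure-white band", {
  strip <- makeTextureImage(c(26, 180), seed = 4)
  expect_identical(addSpacer(strip, 0), strip)
  ext <- addSpacer(strip, 15)
  expect_identical(dim(ext), c(41L, 180L, 3L))
  expect_true(all(ext[27:41, , ] == 1))
  expect_identical(ext[1:26, , ], strip)
})

test_that("polarRing maps uniform strips to rotationally uniform rings", {
  strip <- array(0.5, c(20, 100, 3))
  strip[1:10, , 1] <- 0.7
  ring <- polarRing(strip, 256)
  lum <- illusionflow:::.luma(ring)
  ctr <- (256 + 1) / 2
  angs <- seq(0, 2 * pi, length.out = 361)[-361]
  for (rr in c(60, 100, 120)) {
    vals <- illusionflow:::.bilinearSample(lum, ctr - rr * sin(angs),
                                           ctr + rr * cos(angs))
    expect_lt(sd(vals), 1e-3)
  }
})

test_that("a single dark column becomes a single radial spoke", {
  strip <- array(0.9, c(16, 120, 3))
  strip[, 31, ] <- 0                              # one black column
  ring <- polarRing(strip, 200)
  lum <- illusionflow:::.luma(ring)
  ctr <- (200 + 1) / 2
  angs <- seq(0, 2 * pi, length.out = 721)[-721]
  vals <- illusionflow:::.bilinearSample(lum, ctr - 80 * sin(angs),
                                         ctr + 80 * cos(angs))
  dark <- which(vals < 0.5)
  expect_gt(length(dark), 0)
  expect_lt(diff(range(angs[dark])), 0.2)         # one contiguous dark sector
})

test_that("the mapped arc length at the patch mid-line matches the strip length", {
  img <- makeIllusionImage(seed = 2)
  for (crop in list(c(76, 30, 9, 26), c(70, 40, 8, 18))) {
    d <- makeRingDesign(img, crop = crop, nS = 20, outSize = 512)
    x <- d@spec@x; y <- d@spec@y; h <- d@spec@h
    u <- (20 * x / pi - y) / 2
    # geometry of the warp: bottom row sits at u - h, so the patch mid-line
    # radius is u + y/2 and its mapped circumference is 2*pi*(u + y/2)
    arc <- 2 * pi * (u + y / 2)
    expect_lt(abs(arc - 20 * x) / (20 * x), 0.02)
    # and the printed RingSpec radius obeys the floor-error bound
    expect_lt(abs(20 * x - 2 * pi * d@spec@r), 2 * pi)
  }
})

test_that("mirrorVariant is an involution and mirrors the warped ring", {
  patch <- makeTextureImage(c(26, 9), seed = 6)
  expect_identical(mirrorVariant(mirrorVariant(patch)), patch)
  sym <- patch
  sym[, , ] <- (patch + mirrorVariant(patch)) / 2  # symmetric patch
  expect_identical(mirrorVariant(sym), sym)

  img <- makeIllusionImage(seed = 2)
  d1 <- makeRingDesign(img, crop = c(76, 30, 9, 26), outSize = 512)
  d2 <- makeRingDesign(img, crop = c(76, 30, 9, 26), mirror = TRUE,
                       outSize = 512)
  flipped <- d2@ring[, rev(seq_len(dim(d2@ring)[2])), , drop = FALSE]
  expect_lt(mean(abs(d1@ring - flipped)), 2 / 255)
})

test_that("composeStimulus centres the ring on a white 160x120 canvas", {
  ring <- makeRingDesign(makeIllusionImage(seed = 2),
                         crop = c(76, 30, 9, 26), outSize = 256)@ring
  canvas <- composeStimulus(ring)
  expect_identical(dim(canvas), c(120L, 160L, 3L))
  expect_true(all(canvas[, 1:20, ] == 1))          # white margins
  expect_true(all(canvas[, 141:160, ] == 1))
  expect_true(all(canvas[1, 1, ] == 1) && all(canvas[120, 160, ] == 1))
  white <- composeStimulus(array(1, c(64, 64, 3)))
  expect_true(all(white == 1))
})

test_that("unwarping the ring mid-radius recovers the tiling frequency", {
  img <- makeIllusionImage(seed = 2)
  d <- makeRingDesign(img, crop = c(76, 30, 9, 26), nS = 20, outSize = 512)
  lum <- illusionflow:::.luma(d@ring)
  ctr <- (512 + 1) / 2
  # radius of the patch mid-line in output pixels
  u <- (20 * 9 / pi - 26) / 2
  scale <- (512 / 2) / ((u - d@spec@h) + 26 + d@spec@h)
  rr <- (u + 26 / 2) * scale
  M <- 720
  angs <- seq(0, 2 * pi, length.out = M + 1)[-(M + 1)]
  prof <- illusionflow:::.bilinearSample(lum, ctr - rr * sin(angs),
                                         ctr + rr * cos(angs))
  spec <- Mod(fft(prof - mean(prof)))[2:(M / 2)]
  expect_identical(which.max(spec), 20L)           # dominant harmonic = nS
})

test_that("out-of-bounds crops and undersized outputs are flagged", {
  img <- makeIllusionImage(seed = 2)
  expect_error(makeRingDesign(img, crop = c(155, 30, 9, 26)), "bounds")
  expect_warning(polarRing(array(0.5, c(64, 100, 3)), outSize = 32),
                 "undersampled")
})
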