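# Feature detection and sparse/dense optical flow.

test_that("detectFeatures finds square corners and nothing on uniform images", {
  expect_identical(nrow(detectFeatures(array(0.5, c(40, 40, 3)))), 0L)

  img <- array(0, c(40, 40, 3))
  img[15:26, 15:26, ] <- 1                       # white square on black
  pts <- detectFeatures(img, qualityLevel = 0.3, maxN = 20)
  expect_identical(nrow(pts), 4L)
  corners <- rbind(c(14, 14), c(25, 14), c(14, 25), c(25, 25))
  for (i in seq_len(4)) {
    d <- sqrt((pts$x - corners[i, 1])^2 + (pts$y - corners[i, 2])^2)
    expect_lt(min(d), 2.1)                       # one point adjacent to each corner
  }
  # quality level 1: only global-maximum response survives
  ptsTop <- detectFeatures(img, qualityLevel = 1, maxN = 20)
  expect_true(all(ptsTop$response == max(pts$response)))
  expect_true(nrow(ptsTop) <= nrow(pts))
})

test_that("detectFeatures agrees with a brute-force corner-response oracle", {
  img <- makeTextureImage(c(30, 30), sigma = 1.5, seed = 12)
  pts <- detectFeatures(img, qualityLevel = 0.5, maxN = 5, blockSize = 3)
  # oracle: explicit loops over pixels, same gradient/window definitions
  g <- illusionflow:::.toFlowGray(img)
  H <- nrow(g); W <- ncol(g)
  gx <- gy <- matrix(0, H, W)
  for (y in 1:H) for (x in 1:W) {
    gx[y, x] <- (g[y, min(x + 1, W)] - g[y, max(x - 1, 1)]) / 2
    gy[y, x] <- (g[min(y + 1, H), x] - g[max(y - 1, 1), x]) / 2
  }
  resp <- matrix(0, H, W)
  for (y in 2:(H - 1)) for (x in 2:(W - 1)) {
    sxx <- sxy <- syy <- 0
    for (dy in -1:1) for (dx in -1:1) {
      sxx <- sxx + gx[y + dy, x + dx]^2
      syy <- syy + gy[y + dy, x + dx]^2
      sxy <- sxy + gx[y + dy, x + dx] * gy[y + dy, x + dx]
    }
    resp[y, x] <- ((sxx + syy) - sqrt((sxx - syy)^2 + 4 * sxy^2)) / 2
  }
  for (i in seq_len(nrow(pts)))
    expect_equal(pts$response[i], resp[pts$y[i] + 1, pts$x[i] + 1],
                 tolerance = 1e-10)
})

test_that("sparse flow is zero on identical images and recovers translations", {
  img <- makeTextureImage(c(120, 160), sigma = 2, seed = 3)
  pts <- detectFeatures(img, 0.3, 60)
  same <- sparseFlow(img, img, pts)
  expect_true(all(flowMagnitudes(same) < 1e-3))

  fx <- makeFlowFixture(img, 3, 0)
  fl <- sparseFlow(fx$a, fx$b, pts)
  v <- flowVectors(fl)
  expect_gt(nrow(v), 5)
  expect_lt(sqrt((mean(v$dx) - 3)^2 + mean(v$dy)^2), 0.25)
})

test_that("sparse flow on a rotated image is predominantly tangential", {
  img <- makeTextureImage(c(120, 160), sigma = 2, seed = 15)
  ang <- 2 * pi / 180
  H <- 120; W <- 160; cy <- (H + 1) / 2; cx <- (W + 1) / 2
  XS <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  YS <- matrix(seq_len(H), H, W) - cy
  rot <- illusionflow:::.warpImage(img, cy + sin(-ang) * XS + cos(ang) * YS,
                                   cx + cos(ang) * XS - sin(-ang) * YS,
                                   "reflect")
  pts <- detectFeatures(img, 0.2, 80)
  v <- flowVectors(sparseFlow(img, rot, pts))
  v <- v[v$magnitude > 0.05, ]
  rx <- v$start_x + 1 - cx; ry <- v$start_y + 1 - cy
  rn <- sqrt(rx^2 + ry^2)
  radial <- abs((v$dx * rx + v$dy * ry) / rn)
  tangential <- abs((v$dx * (-ry) + v$dy * rx) / rn)
  expect_lt(mean(radial), mean(tangential))
})

test_that("dense flow: identity is empty, translations are recovered, grid respected", {
  img <- makeTextureImage(c(120, 160), sigma = 2, seed = 5)
  expect_identical(nrow(flowVectors(denseFlow(img, img))), 0L)

  fx <- makeFlowFixture(img, 2, 1)
  fl <- denseFlow(fx$a, fx$b)
  v <- flowVectors(fl)
  expect_lte(nrow(v), 32 * 24)
  expect_true(all(v$start_x %% 5 == 0) && all(v$start_y %% 5 == 0))
  expect_true(all(v$magnitude >= 0.01))
  expect_lt(sqrt((mean(v$dx) - 2)^2 + (mean(v$dy) - 1)^2), 0.25)

  # min_vec filtering is monotone
  n1 <- nrow(flowVectors(denseFlow(fx$a, fx$b, minVec = 0.01)))
  n2 <- nrow(flowVectors(denseFlow(fx$a, fx$b, minVec = 0.5)))
  expect_lte(n2, n1)
})

test_that("dense flow resolves a subpixel translation", {
  img <- makeTextureImage(c(120, 160), sigma = 2, seed = 6)
  fx <- makeFlowFixture(img, 0.5, 0)
  v <- flowVectors(denseFlow(fx$a, fx$b))
  expect_gt(mean(v$dx), 0.25)
  expect_lt(mean(v$dx), 0.75)
})

test_that("flow CSV round-trips and the overlay renderer marks start points", {
  img <- makeTextureImage(c(60, 80), sigma = 2, seed = 8)
  fx <- makeFlowFixture(img, 1.5, -0.5)
  fl <- denseFlow(fx$a, fx$b)
  path <- tempfile(fileext = ".csv")
  writeFlowCSV(fl, path)
  hdr <- names(read.csv(path))
  expect_identical(hdr, c("start_x", "start_y", "dx", "dy", "magnitude", "method"))
  fl2 <- readFlowCSV(path, c(60L, 80L))
  expect_equal(fl2@vectors, fl@vectors, tolerance = 1e-12)
  expect_identical(fl2@method, "dense")

  ov <- renderFlowOverlay(img, fl)
  v1 <- flowVectors(fl)[1, ]
  px <- ov[v1$start_y + 1, v1$start_x + 1, ]
  expect_equal(as.numeric(px), c(1, 1, 0))       # yellow start point
})

test_that("mismatched image shapes are rejected", {
  a <- makeTextureImage(c(40, 40), seed = 1)
  b <- makeTextureImage(c(40, 60), seed = 1)
  expect_error(sparseFlow(a, b, data.frame(x = 10, y = 10)), "identical dim")
  expect_error(denseFlow(a, b), "identical dim")
})
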