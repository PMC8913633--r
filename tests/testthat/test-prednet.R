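# The predictive-coding network core: state initialisation, forward-pass
# contract, a scalar-loop oracle of the conv-LSTM update equations, gradient
# correctness, training behaviour and model serialization.

test_that("initState returns all-zero state and enforces the config contract", {
  cfg <- prednetConfig(nLayers = 2L, channels = c(4L, 6L),
                       inputShape = c(16L, 16L, 3L))
  st <- initState(cfg)
  expect_s3_class(st, "PredictorState")
  expect_identical(st$step, 0L)
  expect_true(all(vapply(st$H, function(x) all(x == 0), TRUE)))
  expect_true(all(vapply(st$E, function(x) all(x == 0), TRUE)))
  expect_identical(initState(cfg), st)   # deterministic

  expect_error(prednetConfig(nLayers = 2L, channels = 4L,
                             inputShape = c(16L, 16L, 3L)),
               "one entry per layer")
  expect_error(prednetConfig(nLayers = 3L, channels = c(2L, 2L, 2L),
                             inputShape = c(10L, 16L, 3L)),
               "divisible")
})

test_that("forwardStep keeps its contract: shapes, determinism, non-negative errors", {
  cfg <- prednetConfig(nLayers = 2L, channels = c(3L, 4L),
                       inputShape = c(8L, 8L, 3L), seed = 3L)
  m <- untrainedModel(cfg)
  st <- initState(cfg)
  fr <- randomFrame(seed = 2L)
  r1 <- forwardStep(m, st, fr)
  r2 <- forwardStep(m, st, fr)
  expect_identical(r1$prediction, r2$prediction)
  expect_identical(dim(r1$prediction), dim(fr))
  expect_true(min(r1$prediction) >= 0 && max(r1$prediction) <= 1)
  for (E in r1$errors) expect_true(min(E) >= 0)
  expect_identical(r1$state$step, 1L)
  expect_error(forwardStep(m, st, array(0, c(4, 4, 3))), "shape")
  expect_error(forwardStep(m, st, fr + 2), "\\[0, 1\\]")
})

test_that("forward pass matches an independent scalar-loop conv-LSTM oracle", {
  # 2x2 single-layer network with 1x1 kernels and hand-set weights; the
  # oracle implements the error-split and LSTM equations with plain loops.
  cfg <- prednetConfig(nLayers = 1L, channels = 2L, inputShape = c(2L, 2L, 1L),
                       kernelSize = 1L, seed = 5L)
  m <- untrainedModel(cfg)
  set.seed(99)
  m@weights[[1]]$Wx <- matrix(rnorm(2 * 8), 2, 8)    # 2 error ch -> 4 gates x 2
  m@weights[[1]]$Wh <- matrix(rnorm(2 * 8), 2, 8)
  m@weights[[1]]$b  <- rnorm(8)
  m@weights[[1]]$Wp <- matrix(rnorm(2 * 1), 2, 1)
  m@weights[[1]]$bp <- rnorm(1)

  sig <- function(x) 1 / (1 + exp(-x))
  oracle <- function(frames) {
    H <- matrix(0, 4, 2); C <- matrix(0, 4, 2)   # 4 pixels x 2 channels
    Ahat <- rep(0, 4)
    for (fr in frames) {
      a <- as.vector(fr)
      pred <- Ahat
      for (px in 1:4) {
        e <- c(max(a[px] - Ahat[px], 0), max(Ahat[px] - a[px], 0))
        z <- as.vector(e %*% m@weights[[1]]$Wx) +
             as.vector(H[px, ] %*% m@weights[[1]]$Wh) + m@weights[[1]]$b
        i <- sig(z[1:2]); f <- sig(z[3:4]); o <- sig(z[5:6]); g <- tanh(z[7:8])
        C[px, ] <- f * C[px, ] + i * g
        H[px, ] <- o * tanh(C[px, ])
      }
      Ahat <- vapply(1:4, function(px)
        min(max(sum(H[px, ] * m@weights[[1]]$Wp[, 1]) + m@weights[[1]]$bp, 0), 1),
        0)
    }
    Ahat
  }

  set.seed(123)
  frames <- lapply(1:3, function(i) array(runif(4), c(2, 2, 1)))
  st <- initState(cfg)
  for (fr in frames) {
    r <- forwardStep(m, st, fr)
    st <- r$state
  }
  expect_lt(max(abs(as.vector(r$prediction) - oracle(frames))), 1e-6)
})

test_that("BPTT gradients agree with finite differences", {
  cfg <- prednetConfig(nLayers = 2L, channels = c(2L, 3L),
                       inputShape = c(8L, 8L, 3L), kernelSize = 3L,
                       lossWeights = c(1, 0.3), seed = 42L)
  w <- illusionflow:::.initWeights(cfg)
  frames <- lapply(1:3, function(i) randomFrame(seed = 100 + i))
  sg <- illusionflow:::.seqGrads(cfg, w, frames)
  lossAt <- function(w) illusionflow:::.seqGrads(cfg, w, frames)$loss
  eps <- 1e-6
  set.seed(1)
  for (l in 1:2) for (nm in c("Wx", "Wh", "b", "Wp")) {
    idx <- sample(length(w[[l]][[nm]]), 3)
    for (ii in idx) {
      wp <- w; wp[[l]][[nm]][ii] <- wp[[l]][[nm]][ii] + eps
      wm <- w; wm[[l]][[nm]][ii] <- wm[[l]][[nm]][ii] - eps
      num <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
      expect_lt(abs(num - sg$grads[[l]][[nm]][ii]) /
                  max(abs(num) + abs(sg$grads[[l]][[nm]][ii]), 1e-6), 1e-3)
    }
  }
})

test_that("training reduces loss on a constant video and is seed-deterministic", {
  cfg <- tinyConfig()
  frames <- rep(list(randomFrame(seed = 4L)), 8L)
  m <- trainPredNet(cfg, frames, epochs = 10L)
  tr <- lossTrace(m)
  expect_lte(tr[length(tr)], tr[1])

  m2 <- trainPredNet(cfg, frames, epochs = 10L)
  expect_identical(lossTrace(m2), tr)          # bit-identical loss trace
  expect_identical(m2@weights, m@weights)

  m3 <- trainPredNet(cfg, frames, epochs = 3L, learningRate = 0)
  expect_identical(m3@weights, untrainedModel(cfg)@weights)

  expect_error(trainPredNet(cfg, list()), "at least 2 frames")
  expect_error(trainPredNet(cfg, frames[1]), "at least 2 frames")
})

test_that("a model trained on drifting texture beats the copy-last-frame baseline", {
  cfg <- prednetConfig(nLayers = 1L, channels = 8L, inputShape = c(48L, 64L, 3L),
                       learningRate = 0.01, seed = 11L)
  vid <- makeTrainingVideo("drifting_texture", nFrames = 150L,
                           frameSize = c(48L, 64L), velocity = c(2, 0),
                           seed = 4L)
  m <- trainPredNet(cfg, vid$frames[1:110], epochs = 4L, seqLen = 10L)
  held <- vid$frames[111:150]
  expect_lt(evaluateNextFrameMSE(m, held, warmup = 5L),
            copyLastBaselineMSE(held, warmup = 5L))
})

test_that("error units stay non-negative across a rollout", {
  cfg <- prednetConfig(nLayers = 2L, channels = c(3L, 4L),
                       inputShape = c(8L, 8L, 3L), seed = 13L)
  m <- untrainedModel(cfg)
  st <- initState(cfg)
  for (i in 1:5) {
    r <- forwardStep(m, st, randomFrame(seed = i))
    st <- r$state
    expect_true(all(vapply(r$errors, function(E) min(E) >= 0, TRUE)))
  }
})

test_that("save/load round-trips a model bit-exactly", {
  cfg <- tinyConfig()
  m <- trainPredNet(cfg, lapply(1:6, randomFrame, shape = c(8L, 8L, 3L)),
                    epochs = 2L)
  probe <- randomFrame(seed = 50L)
  p0 <- forwardStep(m, initState(cfg), probe)$prediction
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(m2@weights, m@weights)
  expect_identical(forwardStep(m2, initState(cfg), probe)$prediction, p0)

  expect_error(loadModel(tempfile()), "does not exist")
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(loadModel(bad), "not an illusionflow model")
  other <- prednetConfig(nLayers = 1L, channels = 6L,
                         inputShape = c(8L, 8L, 3L))
  expect_error(loadModel(path, config = other), "config mismatch")
  expect_silent(loadModel(path, config = cfg))
})

test_that("training on static-containing video improves static-probe convergence", {
  cfg <- prednetConfig(nLayers = 1L, channels = 6L, inputShape = c(32L, 32L, 3L),
                       learningRate = 0.01, seed = 21L)
  vid <- makeTrainingVideo("static_segments", nFrames = 60L,
                           frameSize = c(32L, 32L), seed = 8L)
  m <- trainPredNet(cfg, vid$frames, epochs = 4L, seqLen = 10L)
  gray <- array(0.5, c(32L, 32L, 3L))
  errTrained <- mean(abs(predictPair(m, gray)@p1 - gray))
  errUntrained <- mean(abs(predictPair(untrainedModel(cfg, seed = 77L), gray)@p1 - gray))
  expect_lt(errTrained, errUntrained)
})
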