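# Hierarchical predictive-coding network (convolutional-LSTM hierarchy fed
# with prediction errors).
#
# Layer l = 1 is the pixel layer. One time step, on consuming frame t:
#   bottom-up   A_1 = frame;  E_l = [relu(A_l - Ahat_l), relu(Ahat_l - A_l)]
#               A_{l+1} = maxpool2(relu(conv(E_l)))
#   top-down    X_l = [E_l, upsample2(H_{l+1})]  (E_L alone at the top)
#               (H_l, C_l) <- convLSTM(X_l, H_l, C_l)
#   predict     Ahat_l = relu(conv(H_l));  pixel layer clamped to [0, 1]
# where Ahat_l entering the step is the prediction made at step t - 1, so the
# error units always compare the current frame against the standing
# prediction, and only errors (never raw frames) feed the LSTMs. The value
# returned by a step is the network's prediction of the *next* frame.
#
# Training loss (per sequence, steps t = 2..T):
#   mean_t [ w_1 * mse(frame_t, Ahat_1^(t-1)) + sum_{l>1} w_l * mean(E_l(t)^2) ]

.targetChannels <- function(cfg) {
  a <- cfg@channels
  a[1] <- cfg@inputShape[3]
  a
}

.layerDims <- function(cfg) {
  lapply(seq_len(cfg@nLayers) - 1L,
         function(s) as.integer(cfg@inputShape[1:2] / 2L^s))
}

.lstmInputChannels <- function(cfg) {
  L <- cfg@nLayers
  a <- .targetChannels(cfg)
  vapply(seq_len(L), function(l)
    2L * a[l] + if (l < L) cfg@channels[l + 1L] else 0L, integer(1))
}

.concatC <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

.initWeights <- function(cfg) {
  k <- cfg@kernelSize; L <- cfg@nLayers
  a <- .targetChannels(cfg); cx <- .lstmInputChannels(cfg)
  mk <- function(cin, cout) {
    matrix(rnorm(k * k * cin * cout, sd = 1 / sqrt(k * k * cin)),
           k * k * cin, cout)
  }
  .withSeed(cfg@seed, {
    lapply(seq_len(L), function(l) {
      ch <- cfg@channels[l]
      b <- rep(0, 4 * ch)
      b[ch + seq_len(ch)] <- 1          # forget-gate bias
      wl <- list(Wx = mk(cx[l], 4L * ch), Wh = mk(ch, 4L * ch), b = b,
                 Wp = mk(ch, a[l]), bp = rep(0, a[l]))
      if (l > 1L) {
        wl$Wa <- mk(2L * a[l - 1L], a[l])
        wl$ba <- rep(0, a[l])
      }
      wl
    })
  })
}

.freshState <- function(cfg) {
  dims <- .layerDims(cfg); a <- .targetChannels(cfg)
  L <- cfg@nLayers
  st <- list(
    H    = lapply(seq_len(L), function(l) .zeros(dims[[l]][1], dims[[l]][2], cfg@channels[l])),
    C    = lapply(seq_len(L), function(l) .zeros(dims[[l]][1], dims[[l]][2], cfg@channels[l])),
    Ahat = lapply(seq_len(L), function(l) .zeros(dims[[l]][1], dims[[l]][2], a[l])),
    E    = lapply(seq_len(L), function(l) .zeros(dims[[l]][1], dims[[l]][2], 2L * a[l])),
    step = 0L)
  class(st) <- "PredictorState"
  st
}

.lstmCell <- function(X, Hold, Cold, wl, k, cache = FALSE) {
  z <- .conv2d(X, wl$Wx, wl$b, k) + .conv2d(Hold, wl$Wh, rep(0, length(wl$b)), k)
  n <- dim(z)[3] %/% 4L
  i <- .sigmoid(z[, , seq_len(n), drop = FALSE])
  f <- .sigmoid(z[, , n + seq_len(n), drop = FALSE])
  o <- .sigmoid(z[, , 2L * n + seq_len(n), drop = FALSE])
  g <- tanh(z[, , 3L * n + seq_len(n), drop = FALSE])
  Cn <- f * Cold + i * g
  tC <- tanh(Cn)
  Hn <- o * tC
  out <- list(H = Hn, C = Cn)
  if (cache)
    out$cache <- list(X = X, Hold = Hold, Cold = Cold, i = i, f = f, o = o,
                      g = g, tanhCn = tC)
  out
}

.lstmCellBack <- function(dH, dC, cc, wl, k) {
  tC <- cc$tanhCn
  do  <- dH * tC
  dCn <- dC + dH * cc$o * (1 - tC^2)
  dzi <- (dCn * cc$g) * cc$i * (1 - cc$i)
  dzf <- (dCn * cc$Cold) * cc$f * (1 - cc$f)
  dzo <- do * cc$o * (1 - cc$o)
  dzg <- (dCn * cc$i) * (1 - cc$g^2)
  dz <- .concatC(.concatC(dzi, dzf), .concatC(dzo, dzg))
  bx <- .conv2dBack(dz, cc$X, wl$Wx, k)
  bh <- .conv2dBack(dz, cc$Hold, wl$Wh, k)
  list(dWx = bx$dW, db = bx$db, dX = bx$dx,
       dWh = bh$dW, dHold = bh$dx, dCold = dCn * cc$f)
}

.fwdStep <- function(cfg, w, st, frame, cache = FALSE) {
  L <- cfg@nLayers; k <- cfg@kernelSize
  A <- vector("list", L); E <- vector("list", L)
  aCache <- vector("list", L)
  A[[1]] <- frame
  for (l in seq_len(L)) {
    diff <- A[[l]] - st$Ahat[[l]]
    E[[l]] <- .concatC(pmax(diff, 0), pmax(-diff, 0))
    if (l < L) {
      z <- .conv2d(E[[l]], w[[l + 1]]$Wa, w[[l + 1]]$ba, k)
      mp <- .maxpool2(pmax(z, 0))
      A[[l + 1]] <- mp$out
      if (cache) aCache[[l + 1]] <- list(z = z, idx = mp$idx)
    }
  }
  Hn <- vector("list", L); Cn <- vector("list", L)
  lstmCache <- vector("list", L)
  for (l in L:1) {
    X <- if (l < L) .concatC(E[[l]], .upsample2(Hn[[l + 1]])) else E[[l]]
    cell <- .lstmCell(X, st$H[[l]], st$C[[l]], w[[l]], k, cache)
    Hn[[l]] <- cell$H; Cn[[l]] <- cell$C
    if (cache) lstmCache[[l]] <- cell$cache
  }
  Ahat <- vector("list", L); pz <- vector("list", L)
  for (l in seq_len(L)) {
    z <- .conv2d(Hn[[l]], w[[l]]$Wp, w[[l]]$bp, k)
    Ahat[[l]] <- if (l == 1L) pmin(pmax(z, 0), 1) else pmax(z, 0)
    if (cache) pz[[l]] <- z
  }
  newSt <- list(H = Hn, C = Cn, Ahat = Ahat, E = E, step = st$step + 1L)
  class(newSt) <- "PredictorState"
  res <- list(state = newSt, prediction = Ahat[[1]], errors = E)
  if (cache)
    res$cache <- list(frame = frame, AhatPrev = st$Ahat, A = A, E = E,
                      aCache = aCache, lstm = lstmCache, Hn = Hn, pz = pz)
  res
}

# Loss and weight gradients over one frame sequence (truncated BPTT from a
# fresh state).
.seqGrads <- function(cfg, w, frames) {
  L <- cfg@nLayers; k <- cfg@kernelSize
  a <- .targetChannels(cfg)
  lw <- cfg@lossWeights
  T <- length(frames)
  denom <- max(T - 1L, 1L)

  st <- .freshState(cfg)
  caches <- vector("list", T)
  loss <- 0
  for (t in seq_len(T)) {
    r <- .fwdStep(cfg, w, st, frames[[t]], cache = TRUE)
    caches[[t]] <- r$cache
    if (t >= 2L) {
      loss <- loss + lw[1] * mean((frames[[t]] - r$cache$AhatPrev[[1]])^2) / denom
      if (L > 1L) for (l in 2:L) if (lw[l] != 0)
        loss <- loss + lw[l] * mean(r$cache$E[[l]]^2) / denom
    }
    st <- r$state
  }

  g <- rapply(w, function(m) m * 0, how = "replace")
  zerosLike <- function(x) lapply(x, function(v) array(0, dim(v)))
  carryAhat <- zerosLike(st$Ahat)
  carryH <- zerosLike(st$H)
  carryC <- zerosLike(st$C)

  for (t in T:1) {
    cc <- caches[[t]]
    # (a) prediction convolutions; grads w.r.t. Ahat produced at step t come
    # from step t + 1 (carryAhat)
    dHn <- zerosLike(carryH)
    for (l in seq_len(L)) {
      z <- cc$pz[[l]]
      gate <- if (l == 1L) (z > 0 & z < 1) else (z > 0)
      dz <- carryAhat[[l]] * gate
      bb <- .conv2dBack(dz, cc$Hn[[l]], w[[l]]$Wp, k)
      g[[l]]$Wp <- g[[l]]$Wp + bb$dW
      g[[l]]$bp <- g[[l]]$bp + bb$db
      dHn[[l]] <- dHn[[l]] + bb$dx
    }
    # (b) LSTMs, ascending so that layer l's X-gradient reaches H_{l+1}
    # before layer l + 1 is processed
    dE <- zerosLike(cc$E)
    newCarryH <- vector("list", L); newCarryC <- vector("list", L)
    for (l in seq_len(L)) {
      cb <- .lstmCellBack(dHn[[l]] + carryH[[l]], carryC[[l]],
                          cc$lstm[[l]], w[[l]], k)
      g[[l]]$Wx <- g[[l]]$Wx + cb$dWx
      g[[l]]$Wh <- g[[l]]$Wh + cb$dWh
      g[[l]]$b  <- g[[l]]$b + cb$db
      newCarryH[[l]] <- cb$dHold
      newCarryC[[l]] <- cb$dCold
      nE <- 2L * a[l]
      dE[[l]] <- dE[[l]] + cb$dX[, , seq_len(nE), drop = FALSE]
      if (l < L) {
        extra <- cb$dX[, , (nE + 1L):dim(cb$dX)[3], drop = FALSE]
        dHn[[l + 1L]] <- dHn[[l + 1L]] + .upsample2Back(extra)
      }
    }
    # (c) loss terms at step t
    dAhatPrev <- zerosLike(cc$AhatPrev)
    if (t >= 2L) {
      N1 <- length(cc$frame)
      dAhatPrev[[1]] <- dAhatPrev[[1]] +
        lw[1] * 2 * (cc$AhatPrev[[1]] - cc$frame) / N1 / denom
      if (L > 1L) for (l in 2:L) if (lw[l] != 0)
        dE[[l]] <- dE[[l]] + lw[l] * 2 * cc$E[[l]] / length(cc$E[[l]]) / denom
    }
    # (d) error units and A-path, descending so that layer l's conv input
    # gradient reaches E_{l-1} before layer l - 1 is processed
    for (l in L:1) {
      al <- a[l]
      dEpos <- dE[[l]][, , seq_len(al), drop = FALSE]
      dEneg <- dE[[l]][, , al + seq_len(al), drop = FALSE]
      diff <- cc$A[[l]] - cc$AhatPrev[[l]]
      mpos <- diff > 0; mneg <- diff < 0
      dA <- dEpos * mpos - dEneg * mneg
      dAhatPrev[[l]] <- dAhatPrev[[l]] - dEpos * mpos + dEneg * mneg
      if (l > 1L) {
        z <- cc$aCache[[l]]$z
        dR <- .maxpool2Back(dA, cc$aCache[[l]]$idx, dim(z)[1], dim(z)[2])
        dz <- dR * (z > 0)
        bb <- .conv2dBack(dz, cc$E[[l - 1L]], w[[l]]$Wa, k)
        g[[l]]$Wa <- g[[l]]$Wa + bb$dW
        g[[l]]$ba <- g[[l]]$ba + bb$db
        dE[[l - 1L]] <- dE[[l - 1L]] + bb$dx
      }
    }
    carryAhat <- dAhatPrev
    carryH <- newCarryH
    carryC <- newCarryC
  }
  list(loss = loss, grads = g)
}

.adamInit <- function(w) {
  list(m = rapply(w, function(x) x * 0, how = "replace"),
       v = rapply(w, function(x) x * 0, how = "replace"),
       t = 0L)
}

.adamStep <- function(w, g, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (l in seq_along(w)) {
    for (nm in names(w[[l]])) {
      opt$m[[l]][[nm]] <- beta1 * opt$m[[l]][[nm]] + (1 - beta1) * g[[l]][[nm]]
      opt$v[[l]][[nm]] <- beta2 * opt$v[[l]][[nm]] + (1 - beta2) * g[[l]][[nm]]^2
      w[[l]][[nm]] <- w[[l]][[nm]] -
        lr * (opt$m[[l]][[nm]] / bc1) / (sqrt(opt$v[[l]][[nm]] / bc2) + eps)
    }
  }
  list(w = w, opt = opt)
}

#' Create a network configuration
#'
#' @param nLayers number of layers in the hierarchy.
#' @param channels integer vector of LSTM hidden channels, one per layer.
#' @param inputShape `c(height, width, channels)` of the input frames;
#'   height and width must be divisible by `2^(nLayers - 1)`.
#' @param kernelSize odd convolution kernel size (default 3).
#' @param learningRate Adam learning rate for [trainPredNet()].
#' @param lossWeights per-layer loss weights; defaults to weight 1 on the
#'   pixel-level mean squared prediction error and 0 elsewhere.
#' @param seed integer seed for weight initialisation.
#' @return a [PredNetConfig-class] object.
#' @examples
#' cfg <- prednetConfig(nLayers = 1, channels = 4, inputShape = c(16, 16, 3))
#' @export
prednetConfig <- function(nLayers = 2L, channels = c(8L, 16L),
                          inputShape = c(120L, 160L, 3L), kernelSize = 3L,
                          learningRate = 0.005, lossWeights = NULL,
                          seed = 1L) {
  if (is.null(lossWeights)) lossWeights <- c(1, rep(0, max(nLayers - 1L, 0L)))
  new("PredNetConfig", nLayers = as.integer(nLayers),
      channels = as.integer(channels), inputShape = as.integer(inputShape),
      kernelSize = as.integer(kernelSize), learningRate = learningRate,
      lossWeights = as.numeric(lossWeights), seed = as.integer(seed))
}

#' Initialise the recurrent state of the network
#'
#' Returns an all-zero `PredictorState`: per-layer LSTM memory and output,
#' per-layer standing predictions and (non-negative, positive/negative
#' rectified) error units, and a frame counter at 0.
#'
#' @param config a [PredNetConfig-class].
#' @return an object of class `PredictorState` (a list).
#' @export
initState <- function(config) {
  stopifnot(is(config, "PredNetConfig"))
  validObject(config)
  .freshState(config)
}

#' @export
print.PredictorState <- function(x, ...) {
  cat(sprintf("PredictorState: %d layer(s), frame counter %d\n",
              length(x$H), x$step))
  invisible(x)
}

.checkFrame <- function(cfg, frame) {
  if (!is.array(frame) || !identical(dim(frame), as.integer(cfg@inputShape)))
    stop("frame must be an array of shape [",
         paste(cfg@inputShape, collapse = ", "), "]", call. = FALSE)
  if (min(frame) < -1e-9 || max(frame) > 1 + 1e-9)
    stop("frame values must lie in [0, 1]", call. = FALSE)
  invisible(frame)
}

#' Advance the network by one frame
#'
#' Consumes one frame and returns the updated state, the network's prediction
#' of the *next* frame (clamped to `[0, 1]`), and the per-layer error-unit
#' tensors (element-wise non-negative). The call is deterministic.
#'
#' @param model a [PredNetModel-class].
#' @param state a `PredictorState` from [initState()] or a previous step.
#' @param frame input frame matching the model's `inputShape`, values in
#'   `[0, 1]`.
#' @return list with elements `state`, `prediction`, `errors`.
#' @export
forwardStep <- function(model, state, frame) {
  stopifnot(is(model, "PredNetModel"))
  .checkFrame(model@config, frame)
  r <- .fwdStep(model@config, model@weights, state, frame)
  r[c("state", "prediction", "errors")]
}

#' Train the predictive-coding network on a frame sequence
#'
#' Minimises the mean squared error between each frame and the standing
#' prediction made at the previous step (plus any configured higher-layer
#' error penalties) by Adam over truncated back-propagation-through-time:
#' the video is cut into consecutive sequences of `seqLen` frames, each
#' started from a fresh state. Deterministic: the same seed, data and config
#' give an identical model and loss trace.
#'
#' @param config a [PredNetConfig-class].
#' @param frames list of `[H, W, C]` arrays in `[0, 1]` (or the `frames`
#'   element of [makeTrainingVideo()] output).
#' @param epochs number of passes over the video.
#' @param seed seed for weight initialisation (defaults to `config@seed`).
#' @param seqLen BPTT sequence length.
#' @param learningRate overrides the config's learning rate if given.
#' @return a [PredNetModel-class] with a per-epoch `lossTrace` in its `meta`.
#' @export
trainPredNet <- function(config, frames, epochs = 1L, seed = config@seed,
                         seqLen = 11L, learningRate = config@learningRate) {
  stopifnot(is(config, "PredNetConfig"))
  validObject(config)
  if (is.array(frames) && length(dim(frames)) == 4L)
    frames <- lapply(seq_len(dim(frames)[4]), function(i) frames[, , , i])
  if (!is.list(frames) || length(frames) < 2L)
    stop("training video must contain at least 2 frames", call. = FALSE)
  lapply(frames, .checkFrame, cfg = config)

  cfg <- config
  cfg@seed <- as.integer(seed)
  w <- .initWeights(cfg)
  opt <- .adamInit(w)

  n <- length(frames)
  starts <- seq(1L, n, by = seqLen)
  chunks <- lapply(starts, function(s) frames[s:min(s + seqLen - 1L, n)])
  chunks <- chunks[vapply(chunks, length, 1L) >= 2L]

  lossTrace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    losses <- numeric(length(chunks))
    for (ci in seq_along(chunks)) {
      sg <- .seqGrads(cfg, w, chunks[[ci]])
      losses[ci] <- sg$loss
      up <- .adamStep(w, sg$grads, opt, learningRate)
      w <- up$w; opt <- up$opt
    }
    lossTrace[ep] <- mean(losses)
  }
  new("PredNetModel", config = cfg, weights = w,
      meta = list(framesSeen = n * epochs, epochs = as.integer(epochs),
                  lossTrace = lossTrace,
                  finalLoss = if (epochs > 0) lossTrace[epochs] else NA_real_,
                  version = 1L))
}

#' Build a model with freshly initialised (untrained) weights
#'
#' Useful as a baseline against trained models.
#' @inheritParams trainPredNet
#' @return a [PredNetModel-class].
#' @export
untrainedModel <- function(config, seed = config@seed) {
  cfg <- config
  cfg@seed <- as.integer(seed)
  new("PredNetModel", config = cfg, weights = .initWeights(cfg),
      meta = list(framesSeen = 0L, epochs = 0L, lossTrace = numeric(0),
                  finalLoss = NA_real_, version = 1L))
}

#' Next-frame prediction error of a model on a frame sequence
#'
#' Runs the model over `frames` from a fresh state and returns the mean
#' squared error between each frame and the prediction issued at the previous
#' step, averaged over steps `(warmup + 1):length(frames)`.
#'
#' @param model a [PredNetModel-class].
#' @param frames list of frames.
#' @param warmup number of initial steps excluded from the average.
#' @return mean squared next-frame prediction error.
#' @seealso [copyLastBaselineMSE()] for the copy-previous-frame reference.
#' @export
evaluateNextFrameMSE <- function(model, frames, warmup = 1L) {
  st <- initState(model@config)
  pred <- NULL
  errs <- c()
  for (t in seq_along(frames)) {
    if (t > warmup && !is.null(pred))
      errs <- c(errs, mean((frames[[t]] - pred)^2))
    r <- forwardStep(model, st, frames[[t]])
    st <- r$state; pred <- r$prediction
  }
  mean(errs)
}

#' @rdname evaluateNextFrameMSE
#' @export
copyLastBaselineMSE <- function(frames, warmup = 1L) {
  errs <- vapply((warmup + 1L):length(frames),
                 function(t) mean((frames[[t]] - frames[[t - 1L]])^2), 0)
  mean(errs)
}

#' Save / load a trained model
#'
#' The on-disk format is a single-file serialized container holding a format
#' tag, a version field, the configuration and all weights; [loadModel()]
#' restores it bit-exactly.
#'
#' @param model a [PredNetModel-class].
#' @param path file path.
#' @param config optional [PredNetConfig-class]; if supplied, [loadModel()]
#'   errors unless it matches the configuration embedded in the file.
#' @return `loadModel` returns the restored [PredNetModel-class];
#'   `saveModel` returns `path` invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "PredNetModel"))
  saveRDS(list(container = "illusionflow-prednet", version = 1L,
               config = .configAsList(model@config), weights = model@weights,
               meta = model@meta), path)
  invisible(path)
}

.configAsList <- function(cfg) {
  list(nLayers = cfg@nLayers, channels = cfg@channels,
       inputShape = cfg@inputShape, kernelSize = cfg@kernelSize,
       learningRate = cfg@learningRate, lossWeights = cfg@lossWeights,
       seed = cfg@seed)
}

.configFromList <- function(x) {
  do.call(prednetConfig, x)
}

#' @rdname saveModel
#' @export
loadModel <- function(path, config = NULL) {
  if (!file.exists(path))
    stop("model file does not exist: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(obj) || !identical(obj$container, "illusionflow-prednet"))
    stop("file is not an illusionflow model container: ", path, call. = FALSE)
  if (!identical(obj$version, 1L))
    stop("unsupported model container version: ", obj$version, call. = FALSE)
  cfg <- .configFromList(obj$config)
  if (!is.null(config) &&
      !identical(.configAsList(config), .configAsList(cfg)))
    stop("config mismatch: the file was saved with a different network ",
         "configuration", call. = FALSE)
  new("PredNetModel", config = cfg, weights = obj$weights, meta = obj$meta)
}

#' @describeIn trainPredNet accessor for the model configuration.
#' @export
modelConfig <- function(model) model@config

#' @describeIn trainPredNet accessor for the per-epoch loss trace.
#' @export
lossTrace <- function(model) model@meta$lossTrace

setMethod("show", "PredNetConfig", function(object) {
  cat(sprintf("PredNetConfig: %d layer(s), channels [%s], input %dx%dx%d, kernel %d\n",
              object@nLayers, paste(object@channels, collapse = ", "),
              object@inputShape[1], object@inputShape[2], object@inputShape[3],
              object@kernelSize))
})

setMethod("show", "PredNetModel", function(object) {
  cat(sprintf("PredNetModel: %d layer(s), %d frames seen, final loss %s\n",
              object@config@nLayers, object@meta$framesSeen,
              format(object@meta$finalLoss, digits = 4)))
})
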