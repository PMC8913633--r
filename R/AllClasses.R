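#' Configuration of the predictive-coding network
#'
#' Holds the architecture and training hyper-parameters of the hierarchical
#' convolutional-LSTM predictive-coding network. Layer 1 is the pixel layer;
#' each higher layer operates at half the spatial resolution of the layer
#' below. `lossWeights[1]` weights the pixel-level mean squared prediction
#' error (the training target); higher-layer weights default to 0 and, when
#' positive, add the mean squared error-unit activity of that layer.
#'
#' @slot nLayers number of layers.
#' @slot channels integer vector, LSTM hidden channels per layer.
#' @slot inputShape integer vector `c(height, width, channels)` of the frames.
#' @slot kernelSize odd convolution kernel size shared by all convolutions.
#' @slot learningRate Adam learning rate used by [trainPredNet()].
#' @slot lossWeights numeric vector, one weight per layer.
#' @slot seed integer seed for weight initialisation.
#'
#' @seealso [prednetConfig()]
#' @export
setClass("PredNetConfig",
  representation(nLayers = "integer", channels = "integer",
                 inputShape = "integer", kernelSize = "integer",
                 learningRate = "numeric", lossWeights = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nLayers < 1L) msg <- c(msg, "nLayers must be >= 1")
    if (length(object@channels) != object@nLayers)
      msg <- c(msg, "channels must have one entry per layer")
    if (any(object@channels < 1L)) msg <- c(msg, "channels must be positive")
    if (length(object@inputShape) != 3L || any(object@inputShape < 1L))
      msg <- c(msg, "inputShape must be c(height, width, channels)")
    if (object@kernelSize %% 2L != 1L || object@kernelSize < 1L)
      msg <- c(msg, "kernelSize must be odd and positive")
    if (length(object@lossWeights) != object@nLayers)
      msg <- c(msg, "lossWeights must have one entry per layer")
    div <- 2L^(object@nLayers - 1L)
    if (object@inputShape[1] %% div != 0L || object@inputShape[2] %% div != 0L)
      msg <- c(msg, sprintf(
        "input height and width must be divisible by %d for %d layers",
        div, object@nLayers))
    if (length(msg)) msg else TRUE
  })

#' A trained predictive-coding network
#'
#' Created by [trainPredNet()] or [loadModel()]. Weights are plain numeric
#' matrices (one im2col-layout matrix per convolution); the forward pass is
#' deterministic given a state and an input frame.
#'
#' @slot config the [PredNetConfig-class] the model was built with.
#' @slot weights per-layer list of convolution weights.
#' @slot meta list with training metadata (`framesSeen`, `epochs`,
#'   `lossTrace`, `finalLoss`, `version`).
#' @export
setClass("PredNetModel",
  representation(config = "PredNetConfig", weights = "list", meta = "list"))

#' The P1/P2 prediction pair for one probe image
#'
#' P1 is the predicted 22nd frame after feeding 21 copies of the probe from a
#' fresh network state; P2 is the predicted 23rd frame after additionally
#' feeding P1 back as the 22nd input.
#'
#' @slot p1,p2 predicted frames, `[H, W, 3]` arrays in `[0, 1]`.
#' @slot probe the probe image.
#' @seealso [predictPair()]
#' @export
setClass("PredictionPair",
  representation(p1 = "array", p2 = "array", probe = "array"),
  validity = function(object) {
    if (!identical(dim(object@p1), dim(object@probe)) ||
        !identical(dim(object@p2), dim(object@probe)))
      "P1 and P2 must have the probe's dimensions" else TRUE
  })

#' A set of optical-flow vectors
#'
#' Start points are 0-based pixel coordinates (`x` along width, `y` along
#' height); displacements are in pixels per predicted-frame step.
#'
#' @slot vectors data.frame with columns `start_x`, `start_y`, `dx`, `dy`.
#' @slot method `"sparse"` or `"dense"`.
#' @slot imageDim integer `c(height, width)` of the source images.
#' @seealso [sparseFlow()], [denseFlow()], [flowMagnitudes()]
#' @export
setClass("FlowField",
  representation(vectors = "data.frame", method = "character",
                 imageDim = "integer"),
  validity = function(object) {
    v <- object@vectors
    msg <- character()
    if (!all(c("start_x", "start_y", "dx", "dy") %in% names(v)))
      msg <- c(msg, "vectors needs columns start_x, start_y, dx, dy")
    else {
      if (nrow(v) && (any(v$start_x < 0) || any(v$start_x > object@imageDim[2] - 1) ||
                      any(v$start_y < 0) || any(v$start_y > object@imageDim[1] - 1)))
        msg <- c(msg, "start points must lie within the image")
      if (nrow(v) && !all(is.finite(c(v$dx, v$dy))))
        msg <- c(msg, "flow components must be finite")
    }
    if (!object@method %in% c("sparse", "dense"))
      msg <- c(msg, "method must be 'sparse' or 'dense'")
    if (length(msg)) msg else TRUE
  })

#' Geometry of a circular illusion-like design
#'
#' For a patch of width `x` and height `y` tiled `nS` times, the white spacer
#' height is `h = floor((nS * x / pi - y) / 2)` so that the strip length
#' `nS * x` matches the circumference `2 * pi * r` of a ring of radius
#' `r = h + y / 2` (decimal values rounded down when deriving `h`).
#'
#' @slot x,y patch width and height in pixels.
#' @slot nS number of repetitions.
#' @slot h spacer height in pixels (integer).
#' @slot r ring radius `h + y / 2` in pixels (real).
#' @slot outSize side of the square polar-warp output.
#' @seealso [spacerHeight()], [makeRingDesign()]
#' @export
setClass("RingSpec",
  representation(x = "integer", y = "integer", nS = "integer", h = "integer",
                 r = "numeric", outSize = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@h < 0L) msg <- c(msg, "spacer height must be >= 0")
    if (abs(object@r - (object@h + object@y / 2)) > 1e-9)
      msg <- c(msg, "r must equal h + y/2")
    if (length(msg)) msg else TRUE
  })

#' A circular illusion-like design and its probe stimulus
#'
#' @slot spec the [RingSpec-class] geometry.
#' @slot ring the polar-warped ring image (`outSize` x `outSize` RGB).
#' @slot stimulus the probe canvas: ring resized to 120 x 120 and centred on
#'   a white 160 x 120 image.
#' @slot variant `"original"` or `"reversed"` (left-right mirrored patch).
#' @export
setClass("RingDesign",
  representation(spec = "RingSpec", ring = "array", stimulus = "array",
                 variant = "character"))

#' A cumulative-Gaussian psychometric fit
#'
#' Models the probability of a counterclockwise (CCW) response as
#' `P(CCW | v) = pnorm((v - mu) / sigma)` where `v` is the physical rotation
#' velocity (deg/s, CCW positive). The rotation-cancellation velocity (the
#' velocity at which CW and CCW responses are equally likely) equals `mu`.
#'
#' @slot mu,sigma fitted parameters (deg/s); `sigma > 0`.
#' @slot rss residual sum of squares of the least-squares fit.
#' @slot cancellationVelocity the velocity at response probability 0.5 (= mu).
#' @slot data the fitted proportions (velocity, n, p, fitted).
#' @seealso [fitPsychometric()], [illusionVelocity()]
#' @export
setClass("PsychometricFit",
  representation(mu = "numeric", sigma = "numeric", rss = "numeric",
                 cancellationVelocity = "numeric", data = "data.frame"),
  validity = function(object)
    if (object@sigma <= 0) "sigma must be > 0" else TRUE)

#' The bias-corrected illusion velocity
#'
#' Combines the rotation-cancellation velocities of the original and the
#' left-right reversed stimulus as
#' `combined = (vReversed - vOriginal) / 2` (deg/s, CCW positive), which
#' cancels any observer response bias common to both stimuli.
#'
#' @slot vOriginal,vReversed cancellation velocities of the two variants.
#' @slot combined the bias-corrected illusion velocity.
#' @seealso [illusionVelocity()]
#' @export
setClass("IllusionVelocity",
  representation(vOriginal = "numeric", vReversed = "numeric",
                 combined = "numeric"))
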