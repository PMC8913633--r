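---
title: "Probing a predictive-coding network for illusory motion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing a predictive-coding network for illusory motion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(illusionflow)
```

# The scientific question

Peripheral-drift motion illusions (the Fraser–Wilcox family and its many
variants) are static designs, typically built from a *repeated unit* of
asymmetric light-to-dark luminance gradients, that most observers perceive
as moving. `illusionflow` operationalises one mechanistic hypothesis: a
visual system whose job is to *predict the next moment* of its input may
predict motion into such patterns. The package provides (i) a predictive
video-prediction network, (ii) a protocol for probing it with static images
and measuring the motion it predicts, (iii) tools to build new circular
illusion-like stimuli out of image regions where the network hallucinates
motion, and (iv) the psychophysical analysis needed to test those stimuli on
observers via rotation nulling.

# The network

The model is a hierarchical predictive-coding network of convolutional LSTM
layers. Layer $l$ maintains a standing prediction $\hat A_l$ of its input
$A_l$; the input to the recurrent units is never the image itself but the
rectified prediction error, split into positive and negative channels:

$$E_l = \left[\,\mathrm{ReLU}(A_l - \hat A_l),\; \mathrm{ReLU}(\hat A_l - A_l)\,\right].$$

On consuming a frame, errors are computed bottom-up ($A_1$ is the frame;
$A_{l+1} = \mathrm{maxpool}_2(\mathrm{ReLU}(\mathrm{conv}(E_l)))$), the
conv-LSTMs update top-down (layer $l$ sees $[E_l, \mathrm{upsample}_2(H_{l+1})]$),
and each layer emits its next prediction
$\hat A_l = \mathrm{ReLU}(\mathrm{conv}(H_l))$, clamped to $[0,1]$ at the
pixel layer. The value returned by a step is therefore the network's
prediction of the *next* frame. Training minimises the mean squared error
between each frame and the prediction issued one step earlier (higher-layer
error penalties are available through `lossWeights` but default to 0),
by Adam over truncated back-propagation-through-time on sequences started
from a fresh state.

Everything architectural is explicit in `prednetConfig()`: layer count,
channel widths, kernel size, input shape, learning rate, loss weights and
the initialisation seed. There is no canonical published configuration for
this probing protocol at desk scale, so none is hard-coded; the defaults
(2 layers, 8/16 channels, 3×3 kernels, 160×120×3 input) are chosen to train
in minutes on one CPU. The implementation is plain R with BLAS-backed
im2col convolutions; its forward pass is checked in the test suite against
an independent scalar-loop implementation of the update equations, and its
gradients against finite differences.

Pixel values are $[0,1]$ internally and 8-bit on disk. Models serialize to a
single-file container with an embedded version field and configuration;
loading is bit-exact, and a mismatched configuration is an explicit error.

# The probing protocol

`predictPair()` feeds 21 copies of one static probe image from a fresh
recurrent state and takes the prediction issued after the 21st frame — the
predicted 22nd frame, **P1**. P1 is then fed back as the 22nd input and the
next prediction is **P2**, the predicted 23rd frame. The state is reset
before each probe (each test image is treated independently), but *not*
between P1 and P2: the P2 computation continues the same rollout, which is
what "using P1 as the 22nd image" implies; a reset variant is deliberately
not offered.

Any systematic displacement between P1 and P2 is motion the network
predicted into a static image. It is quantified two ways:

* **Optical flow** between P1 and P2 (below).
* **Brightness line profiles**: `extractProfile()` reads 0–255 grayscale
  values (standard luma weights, `toGrayscale()`) along a row or column
  segment of the original, P1 and P2 images; `profileShift()` reports the
  signed integer lag maximizing the normalized cross-correlation of two
  profiles over their overlap. Positive means the second profile is
  displaced toward increasing coordinate; ties break toward the smallest
  absolute lag, then positive. Sub-pixel refinement is out of scope — the
  profile shift is a qualitative check, the flow field the quantitative one.
  A constant profile has no defined shift and raises an error, which is why
  the package's "uniform probes move less than illusion probes" regression
  is asserted on mean |P1 − P2| rather than on profile shifts.

# Optical flow

Both estimators convert to grayscale first and share a vectorised iterative
Lucas–Kanade core with a 2-level image pyramid (levels are configurable; the
original analyses' exact pyramid depth is not restated anywhere, so the
default documents itself rather than claiming fidelity):

* `sparseFlow()` starts from Shi–Tomasi-style corner points
  (`detectFeatures()`: structure-tensor minimum eigenvalue, 3×3 non-maximum
  suppression, response ≥ `qualityLevel` × global maximum, deterministic
  descending-response ordering) and solves the local constant-flow
  least-squares problem over a 50-pixel integration window.
* `denseFlow()` evaluates the same local least-squares estimate with a
  10-pixel window at every 5th pixel in x and y and discards vectors with
  magnitude < 0.01. Because each grid point depends only on its own window,
  this equals computing a full dense field and stride-sampling it — the
  package's equivalent of a polynomial-expansion dense method.

Three documented validity rules drop points silently: a near-singular
normal matrix (normalised minimum eigenvalue below `minEig = 1e-4`); a
sparse integration window not fully contained in the image at full
resolution; and a solution whose displacement exceeds the integration
window, which a local constant-flow model cannot legitimately measure (such
iterations diverge on near-uniform regions of blurry predicted frames).
Vector units are pixels per predicted-frame step.

Ground-truth recovery is tested on warped textures: translations of up to
3 px are recovered with mean-vector error below 0.25 px by both methods, a
0.5-px sub-pixel shift lands in (0.25, 0.75), and a 2° rotation yields
predominantly tangential fields.

# Flow statistics

`frequencyHistogram()` bins magnitudes into linear half-open bins of width
0.01 from zero and normalizes rates to sum to 1 over all vectors of an
image group (log-axis display is a plotting choice, not a binning one).
`groupSummary()` reports the per-group mean of per-image mean magnitudes
± SEM (sample-SD/√n; n = images). Images with zero surviving vectors count
as mean 0 — dropping them would silently bias group means upward — and can
also be reported separately. `classifyByFlow()` thresholds per-image means
into "illusion-like" vs "other"; `chooseFlowThreshold()` picks the
accuracy-maximizing midpoint between two labelled groups, breaking ties by
margin.

# The ring designer

A patch of width $x$ and height $y$ is tiled $n_s$ times (default 20) into
a strip of length $n_s x$, and a white spacer band of height

$$h = \left\lfloor \tfrac12\!\left(\tfrac{n_s x}{\pi} - y\right) \right\rfloor$$

is appended below it so the strip length matches the circumference
$2\pi r$ of a ring of radius $r = h + y/2$ (decimals rounded down; the
worked 9×26 and 8×18 patches give $h = 15$ and $16$). `polarRing()`
inverse-maps the strip into a square image (default 1024×1024): columns map
linearly to angle — origin at 3 o'clock, increasing counterclockwise, a
convention that must be fixed somewhere for CW/CCW semantics to mean
anything downstream — and rows map to radius with the patch at the outer
rim and the spacer toward the centre. Sampling is bilinear with angular
wrap-around (nearest-neighbour available for tests needing exactness);
everything outside the annulus is white (255, 255, 255).

One genuinely open design point: with $h$ floored and the strip mapped at
unit radial scale from the centre, the circumference at the patch mid-line
is $2\pi(h + y/2)$, which for the 9×26 patch is 2.3% short of $n_s x$ — the
floor error. `makeRingDesign()` therefore offsets the strip's bottom row to
radius $u - h$ (where $u$ is the unfloored spacer height), placing the patch
mid-line exactly at radius $n_s x / (2\pi)$; the integer $h$ controls only
the white band's height in the strip. The bound
$|n_s x - 2\pi(h + y/2)| < 2\pi$ holds regardless and is asserted in the
tests. Whether the spacer is appended per tile or once under the whole
strip is immaterial for a full-width band; the package appends it to the
tiled strip.

`composeStimulus()` resizes the ring to 120×120 (bilinear) and centres it
on a white 160×120 canvas — the network's input geometry. `mirrorVariant()`
builds the left–right reversed design; the mirrored and original rings are
exact horizontal mirror images up to interpolation (mean absolute
difference < 2/255, tested). `rankCrops()` ranks candidate crop regions by
local mean flow as a convenience, but crop selection for real designs
remains a judgement call and the helper is not validated against any
published choice.

# Psychophysics

The nulling paradigm physically rotates the stimulus to cancel its illusory
rotation. `velocityGrid()` spans −2.1 to +2.1 °/s in 0.3 steps (15
velocities, stored to one decimal to avoid float drift); `makeSchedule()`
crosses them with the original/reversed variants and 30 repetitions (900
trials) in a seeded random order. Presentation geometry (50 cm viewing
distance, 1° gaze point, 7°/1° outer/inner stimulus diameters, 12°
eccentricity, 0.5 s presentation) is metadata of the paradigm, not
simulated; real-time display is out of scope.

`fitPsychometric()` fits $P(\mathrm{CCW}\mid v) = \Phi((v-\mu)/\sigma)$ to
the observed CCW proportions by unweighted least squares on the proportions
(matching how such fits are usually reported; a binomial maximum-likelihood
option exists but is not the default, and weighting by trial count is
deliberately not applied). Initialisation is $\mu_0$ = the velocity whose
proportion is nearest 0.5 and $\sigma_0$ = half the grid span;
optimisation is Levenberg–Marquardt with a Nelder–Mead fallback and a
$\sigma > 0$ floor. All-CW or all-CCW response tables are non-identifiable
and raise an error advising a wider velocity range. The
rotation-cancellation velocity is $\mu$; the bias-corrected illusion
velocity of a design is

$$v_{\mathrm{illusion}} = \tfrac12\,(\mu_{\mathrm{reversed}} - \mu_{\mathrm{original}}),$$

CCW positive: mirroring the design reverses its illusory rotation but not
the observer's response bias, so the half-difference cancels the bias.
`simulateObserver()` provides the synthetic stand-in for human subjects
(per-trial CCW probability $(1-\lambda)\Phi((v-\mu)/\sigma)+\lambda/2$,
lapse $\lambda = 0$ by default, optionally different $\mu$ per stimulus
variant). A 200-replicate recovery study at the default design (30 reps ×
15 velocities, $\mu = 0.4$, $\sigma = 0.4$) recovers $\mu$ with median
absolute error below 0.05 °/s in the test suite.

# Synthetic data: what it emulates and what it does not

The generators replace three external resources: first-person training
video, a curated 1500-image test set, and human observers.

* `makeTrainingVideo()` produces 160×120 RGB frames (the pipeline's fixed
  input contract) with coherent global motion: smooth toroidal textures or
  simple rendered scenes translating at a set velocity, static segments,
  or a mixture. Toroidal textures make wrap-around translation
  artefact-free; `makeFlowFixture()` instead uses reflecting boundaries, as
  a real camera pan would not wrap. Ground-truth displacements are returned
  alongside.
* `makeIllusionImage()` renders concentric rings whose angular luminance is
  a repeating asymmetric sawtooth (direction alternating between radial
  bands), i.e. the repeated-unit gradient structure of the illusion family
  under study; a symmetric triangle unit is the non-directional control.
  The angular spectrum peaks at the requested harmonic (tested by FFT).
* `makeControlImage()` pairs each illusion image with (a) its
  phase-randomized counterpart — identical Fourier amplitudes and mean
  luminance (DC preserved; mean within 2/255 after clipping), no coherent
  structure — and (b) a simple rendered scene shifted to the same mean
  luminance.

What passing tests on these data show: the pipeline's machinery —
training, probing, flow, statistics, geometry, fitting — is correct and
deterministic. What they do not show: that a desk-scale network trained on
minutes of synthetic video perceives illusions as humans do. The shipped
regression freezes observed behaviour at a pinned seed (and indeed the
small default model flags sharp-edged control scenes at least as strongly
as synthetic illusions); reproducing published group-level illusion
statistics requires the original large trained model and stimulus set,
which the package can consume through its image/model-loading path but
does not bundle.

# Problem sizes and numerical choices

The test suite and the end-to-end run (`runSmokePipeline()`) use sizes
chosen as honest desk-scale defaults: a 1-layer, 8-channel network trained
for 2 epochs on 110 frames of mixed synthetic video (truncated BPTT over
11-frame sequences), 3 × 10 probe images, and one 200-replicate observer
study. Unit tests use 8×8 to 64×48 inputs. Tolerances worth knowing:
forward-pass oracle agreement ≤ 1e-6; finite-difference gradient agreement
≤ 1e-3 relative at sampled coordinates; flow ground-truth recovery 0.25 px
(mean vector); ring mirror agreement 2/255 mean absolute; histogram mass
1 ± 1e-9. Degenerate inputs are errors, not guesses: empty magnitude sets
cannot be normalized, constant profiles have no shift, all-one-sided
response tables have no threshold, and a patch too tall for its repetition
count has no non-negative spacer.

# Known limitations

* The network trains in pure R; it is deliberately small. No GPU path, no
  alternative architectures.
* The dense flow method is local least squares on the stride grid, not a
  polynomial-expansion implementation; parameters (window 10, stride 5,
  min_vec 0.01) keep their conventional meanings.
* Sub-pixel profile shifts, occlusion reasoning, colour-channel flow and
  eye-movement modelling are out of scope.
* `rankCrops()` is exploratory; published crop choices were manual.
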