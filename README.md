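# illusionflow

Motion illusions — static designs such as the Fraser–Wilcox family, built
from spatially repeated asymmetric luminance gradients — are perceived as
moving although nothing moves. One influential account ties this to the
brain's predictive machinery: a system trained to predict the next moment of
visual input may "predict" motion into certain static patterns.
`illusionflow` implements that idea as a tested, reusable pipeline in R, for
vision scientists who want to probe a video-prediction network with static
images and quantify where it hallucinates motion:

1. **Predictive-coding network** (`prednetConfig`, `trainPredNet`,
   `forwardStep`): a hierarchical convolutional-LSTM network in which each
   layer holds a standing prediction `Ahat_l` of its input `A_l`, and only
   the rectified prediction errors
   `E_l = [ReLU(A_l − Ahat_l), ReLU(Ahat_l − A_l)]` — never the raw frames —
   propagate forward. Training minimises the pixel-level mean squared error
   between each frame and the prediction issued one step earlier.
2. **Static-image probing** (`predictPair`): feed 21 copies of a probe image
   from a fresh state, take the predicted 22nd frame (**P1**), feed P1 back
   as the 22nd input and take the predicted 23rd frame (**P2**). Any
   systematic P1→P2 displacement is motion the network predicted into a
   static image.
3. **Optical flow** (`detectFeatures`, `sparseFlow`, `denseFlow`): sparse
   feature-based and dense stride-sampled local least-squares flow between
   P1 and P2 (sparse: window 50, quality level 0.3; dense: window 10,
   stride 5, minimum vector 0.01), plus CSV export and an overlay renderer
   (red lines scaled 50× / 4×, yellow start points).
4. **Flow statistics** (`frequencyHistogram`, `groupSummary`,
   `classifyByFlow`): frequency-rate histograms of flow magnitudes (linear
   bin width 0.01, rates summing to 1 per image group), per-group
   mean ± SEM of per-image mean flow, and threshold classification of
   illusion-like images.
5. **Ring designer** (`spacerHeight`, `makeRingDesign`): turn an image patch
   of width `x` and height `y` into a circular illusion-like stimulus: tile
   it `n_s` times, append a white spacer of height
   `h = ⌊(n_s·x/π − y)/2⌋` so the strip length matches the circumference
   `2πr` with `r = h + y/2`, polar-warp the strip into a ring, and compose
   the 160 × 120 probe canvas. Left–right mirrored variants are supported.
6. **Psychophysics** (`makeSchedule`, `simulateObserver`, `fitPsychometric`,
   `illusionVelocity`): two-alternative rotation-nulling analysis. The
   probability of a counterclockwise response is fitted with a cumulative
   Gaussian `P(CCW|v) = Φ((v − μ)/σ)`; the rotation-cancellation velocity is
   `μ`, and the bias-corrected illusion velocity of a design is
   `½(μ_reversed − μ_original)`.
7. **Synthetic data** (`makeTrainingVideo`, `makeIllusionImage`,
   `makeControlImage`, `makeTestGroups`, `makeFlowFixture`): deterministic
   generators for training videos with coherent global motion,
   illusion-style and matched control images, ground-truth flow fixtures and
   simulated observers, so the entire pipeline runs end-to-end with no
   external downloads.

## Worked example

```r
library(illusionflow)

## ring geometry of a 9 x 26 patch tiled 20 times
spacerHeight(9, 26, 20)
#> [1] 15
spacerHeight(8, 18, 20)
#> [1] 16

## recover a known 3-px translation with both flow methods
img <- makeTextureImage(c(120, 160), sigma = 2, seed = 3)
fx  <- makeFlowFixture(img, 3, 0)
v   <- flowVectors(sparseFlow(fx$a, fx$b, detectFeatures(fx$a, 0.3, 100)))
round(c(mean(v$dx), mean(v$dy)), 3)
#> [1] 3.002 -0.001

## a simulated rotation-nulling experiment
sched <- makeSchedule(seed = 1)                       # 900 trials
resp  <- simulateObserver(c(original = -0.3, reversed = 0.3), 0.4,
                          sched, seed = 2)
tab   <- responseTable(resp)
iv <- illusionVelocity(
  fitPsychometric(tab[tab$stimulus_type == "original", ]),
  fitPsychometric(tab[tab$stimulus_type == "reversed", ]))
iv
#> IllusionVelocity: original -0.275, reversed 0.221, combined 0.248 deg/s
```

The simulated observer's psychometric functions were shifted by ∓0.3 °/s for
the original and mirrored design; the recovered bias-corrected illusion
velocity (0.25 °/s, CCW positive) matches the built-in shift up to binomial
trial noise.

The full desk-scale pipeline — train a small network on synthetic video,
probe 30 synthetic images, compute flows, statistics, a ring design and a
psychometric fit — is one call:

```r
res <- runSmokePipeline(outDir = "smoke_out", seed = 1)
res$summary        # per-group mean flow ± SEM, both methods
res$accuracy       # illusion-vs-control separation accuracy
```

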