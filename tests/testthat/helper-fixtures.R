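# Shared fixtures. Heavy artifacts (the desk-scale pipeline run) are built
# once per test run and reused.

.fixtureCache <- new.env(parent = emptyenv())

# The full desk-scale pipeline: small network trained on synthetic mixed
# video, 3 x 10 probe images, flows, statistics, ring design, simulated
# observer fit.
smokeResult <- function() {
  if (is.null(.fixtureCache$smoke)) {
    dir <- file.path(tempdir(), "illusionflow-smoke")
    .fixtureCache$smoke <- runSmokePipeline(outDir = dir, seed = 1L)
  }
  .fixtureCache$smoke
}

smokeModel <- function() {
  if (is.null(.fixtureCache$smokeModel))
    .fixtureCache$smokeModel <- loadModel(smokeResult()$paths$model)
  .fixtureCache$smokeModel
}

tinyConfig <- function(...) {
  prednetConfig(nLayers = 1L, channels = 4L, inputShape = c(8L, 8L, 3L),
                seed = 7L, ...)
}

randomFrame <- function(shape = c(8L, 8L, 3L), seed = 1L) {
  illusionflow:::.withSeed(seed, array(runif(prod(shape)), shape))
}
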