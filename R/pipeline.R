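# Desk-scale end-to-end pipeline on synthetic data.

#' Run the full pipeline end-to-end at desk scale
#'
#' Trains a small predictive-coding network on a synthetic mixed-motion
#' video, probes synthetic illusion and control images for their P1/P2
#' predictions, computes sparse and dense optical flow and the group
#' statistics, builds one ring design from an illusion image, and runs one
#' simulated rotation-nulling experiment with a psychometric fit — writing
#' every artifact format the pipeline defines to `outDir`.
#'
#' @param outDir output directory.
#' @param seed integer master seed for all randomness.
#' @param nPerGroup synthetic test images per group.
#' @param trainFrames training-video length in frames.
#' @param epochs training epochs.
#' @param config network configuration; the default is a deliberately small
#'   single-layer model so the whole run stays in the minutes range on one
#'   CPU.
#' @return list with paths to the artifacts and the key computed numbers
#'   (per-group flow summaries, classification accuracy, psychometric fit).
#' @export
runSmokePipeline <- function(outDir = tempfile("illusionflow"), seed = 1L,
                             nPerGroup = 10L, trainFrames = 110L,
                             epochs = 2L,
                             config = prednetConfig(nLayers = 1L,
                                                    channels = 8L,
                                                    seed = seed)) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # 1. train on synthetic mixed-motion video
  video <- makeTrainingVideo("mixed", nFrames = trainFrames,
                             velocity = c(1, 0), seed = seed)
  model <- trainPredNet(config, video$frames, epochs = epochs, seed = seed)
  paths$model <- file.path(outDir, "model.rds")
  saveModel(model, paths$model)

  # 2. synthetic test groups
  groupsDir <- file.path(outDir, "groups")
  tg <- makeTestGroups(nPerGroup = nPerGroup, dir = groupsDir, seed = seed)
  manifest <- tg$manifest
  paths$manifest <- file.path(groupsDir, "manifest.tsv")

  # 3. probe every image; flows by both methods
  flowDir <- file.path(outDir, "flows")
  predDir <- file.path(outDir, "predictions")
  dir.create(flowDir, showWarnings = FALSE)
  dir.create(predDir, showWarnings = FALSE)
  res <- data.frame(image = basename(manifest$image_path),
                    group = manifest$group_label,
                    meanSparse = NA_real_, meanDense = NA_real_)
  flows <- list()
  for (i in seq_len(nrow(manifest))) {
    img <- tg$images[[basename(manifest$image_path[i])]]
    pair <- predictPair(model, img)
    stem <- sub("\\.png$", "", basename(manifest$image_path[i]))
    writeImageRGB(pair@p1, file.path(predDir, paste0(stem, "_p1.png")))
    writeImageRGB(pair@p2, file.path(predDir, paste0(stem, "_p2.png")))
    fs <- sparseFlow(pair@p1, pair@p2)
    fd <- denseFlow(pair@p1, pair@p2)
    writeFlowCSV(fs, file.path(flowDir, paste0(stem, "_sparse.csv")))
    writeFlowCSV(fd, file.path(flowDir, paste0(stem, "_dense.csv")))
    res$meanSparse[i] <- imageMeanFlow(fs)
    res$meanDense[i] <- imageMeanFlow(fd)
    flows[[stem]] <- list(sparse = fs, dense = fd)
  }
  paths$predictions <- predDir
  paths$flows <- flowDir

  # 4. statistics: frequency histograms per group, group summaries,
  #    threshold classification (illusion vs the pooled controls)
  statsDir <- file.path(outDir, "stats")
  dir.create(statsDir, showWarnings = FALSE)
  for (m in c("sparse", "dense")) {
    for (g in unique(res$group)) {
      stems <- sub("\\.png$", "", res$image[res$group == g])
      mags <- unlist(lapply(stems, function(s) flowMagnitudes(flows[[s]][[m]])))
      if (length(mags)) {
        hist <- frequencyHistogram(mags)
        write.csv(hist, file.path(statsDir, sprintf("hist_%s_%s.csv", g, m)),
                  row.names = FALSE)
      }
    }
  }
  summary <- rbind(cbind(method = "sparse",
                         summarizeGroups(res$meanSparse, res$group)),
                   cbind(method = "dense",
                         summarizeGroups(res$meanDense, res$group)))
  paths$summary <- file.path(statsDir, "group_summary.tsv")
  write.table(summary, paths$summary, sep = "\t", row.names = FALSE,
              quote = FALSE)

  isIll <- res$group == "illusion"
  thr <- chooseFlowThreshold(res$meanDense[isIll], res$meanDense[!isIll])
  labels <- classifyByFlow(res$meanDense, thr)
  accuracy <- mean((labels == "illusion-like") == isIll)
  cls <- cbind(res, label = labels)
  paths$classification <- file.path(statsDir, "classification.tsv")
  write.table(cls, paths$classification, sep = "\t", row.names = FALSE,
              quote = FALSE)

  # 5. one ring design from an illusion image (central crop)
  illName <- res$image[isIll][1]
  illImg <- tg$images[[illName]]
  design <- makeRingDesign(illImg, crop = c(76, 30, 9, 26), nS = 20)
  ringDir <- file.path(outDir, "ring")
  dir.create(ringDir, showWarnings = FALSE)
  writeImageRGB(design@ring, file.path(ringDir, "ring.png"))
  writeImageRGB(design@stimulus, file.path(ringDir, "stimulus.png"))
  jsonlite::write_json(ringSpecAsList(design),
                       file.path(ringDir, "ringspec.json"), auto_unbox = TRUE)
  paths$ring <- ringDir

  # 6. simulated rotation-nulling experiment
  psyDir <- file.path(outDir, "psychophysics")
  dir.create(psyDir, showWarnings = FALSE)
  sched <- makeSchedule(seed = seed)
  write.csv(sched, file.path(psyDir, "schedule.csv"), row.names = FALSE)
  resp <- simulateObserver(c(original = -0.3, reversed = 0.3), 0.4, sched,
                           seed = seed + 1L)
  write.csv(resp, file.path(psyDir, "responses.csv"), row.names = FALSE)
  tab <- responseTable(resp)
  fitO <- fitPsychometric(tab[tab$stimulus_type == "original", ])
  fitR <- fitPsychometric(tab[tab$stimulus_type == "reversed", ])
  iv <- illusionVelocity(fitO, fitR)
  jsonlite::write_json(fitAsList(fitO), file.path(psyDir, "fit_original.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(fitAsList(fitR), file.path(psyDir, "fit_reversed.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(v_original = iv@vOriginal,
                            v_reversed = iv@vReversed,
                            combined = iv@combined),
                       file.path(psyDir, "illusion_velocity.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$psychophysics <- psyDir

  list(paths = paths, perImage = res, summary = summary,
       threshold = thr, accuracy = accuracy,
       fits = list(original = fitO, reversed = fitR, illusion = iv),
       lossTrace = lossTrace(model))
}
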