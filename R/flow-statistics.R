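# Per-image and per-group statistics of optical-flow magnitudes.

#' Magnitudes of the vectors in a flow field
#'
#' @param flow a [FlowField-class] or a data.frame with `dx`, `dy` columns.
#' @return numeric vector of Euclidean norms, order-preserving.
#' @export
flowMagnitudes <- function(flow) {
  v <- if (is(flow, "FlowField")) flow@vectors else flow
  sqrt(v$dx^2 + v$dy^2)
}

#' Mean flow magnitude of one image
#'
#' Arithmetic mean of the vector magnitudes; an image with zero detected
#' vectors contributes mean 0 (documented convention — such images are also
#' countable separately via `nrow(flowVectors(flow)) == 0`).
#'
#' @inheritParams flowMagnitudes
#' @return non-negative scalar.
#' @export
imageMeanFlow <- function(flow) {
  m <- flowMagnitudes(flow)
  if (length(m) == 0L) 0 else mean(m)
}

#' Frequency-rate histogram of flow magnitudes
#'
#' Bins are half-open `[left, left + width)` starting at 0 with the given
#' sampling-window width (default 0.01); a value `v` falls in bin
#' `floor(v / width)`. Rates are normalized so the total over all vectors in
#' the group sums to 1. (Plots of such histograms conventionally use a
#' logarithmic x-axis; the binning itself is linear.)
#'
#' @param magnitudes non-negative numeric vector (all vectors of a group).
#' @param binWidth sampling-window width (> 0), default 0.01.
#' @return data.frame with columns `bin_left`, `count`, `rate`; attribute
#'   `binWidth`.
#' @export
frequencyHistogram <- function(magnitudes, binWidth = 0.01) {
  stopifnot(binWidth > 0)
  if (length(magnitudes) == 0L)
    stop("cannot normalize a histogram of zero vectors", call. = FALSE)
  if (any(magnitudes < 0)) stop("magnitudes must be non-negative", call. = FALSE)
  bin <- floor(magnitudes / binWidth)
  nBins <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = nBins)
  out <- data.frame(bin_left = (seq_len(nBins) - 1L) * binWidth,
                    count = counts, rate = counts / length(magnitudes))
  attr(out, "binWidth") <- binWidth
  out
}

#' Group mean and standard error of per-image mean flows
#'
#' The standard error of the mean uses the sample (n - 1) standard deviation
#' divided by `sqrt(n)`. With a single image the SEM is reported as 0 with a
#' warning.
#'
#' @param perImageMeans numeric vector of per-image mean magnitudes.
#' @param group group label.
#' @return one-row data.frame with `group`, `n`, `mean`, `sem`.
#' @export
groupSummary <- function(perImageMeans, group = "group") {
  n <- length(perImageMeans)
  stopifnot(n >= 1L)
  sem <- if (n == 1L) {
    warning("SEM is undefined for a single image; reporting 0")
    0
  } else sd(perImageMeans) / sqrt(n)
  data.frame(group = group, n = n, mean = mean(perImageMeans), sem = sem)
}

#' Summarise several labelled groups at once
#'
#' @param means numeric vector of per-image mean flows.
#' @param groups group label per image.
#' @return data.frame with one [groupSummary()] row per group.
#' @export
summarizeGroups <- function(means, groups) {
  out <- do.call(rbind, lapply(split(means, groups), function(x)
    groupSummary(x, group = "")))
  out$group <- names(split(means, groups))
  rownames(out) <- NULL
  out[, c("group", "n", "mean", "sem")]
}

#' Threshold classification of images by mean flow
#'
#' An image is labelled `"illusion-like"` iff its mean flow magnitude exceeds
#' the threshold, `"other"` otherwise.
#'
#' @param means per-image mean flow magnitudes.
#' @param threshold non-negative decision threshold.
#' @return character vector of labels.
#' @export
classifyByFlow <- function(means, threshold) {
  stopifnot(threshold >= 0)
  ifelse(means > threshold, "illusion-like", "other")
}

#' Choose a separating threshold between two labelled groups
#'
#' Scans the midpoints between adjacent sorted per-image means and returns
#' the threshold maximizing classification accuracy for
#' `meansIllusion > threshold` vs `meansOther <= threshold`; ties are broken
#' toward the largest margin (distance to the nearest mean).
#'
#' @param meansIllusion,meansOther per-image mean flows of the two groups.
#' @return the selected threshold.
#' @export
chooseFlowThreshold <- function(meansIllusion, meansOther) {
  all <- sort(unique(c(meansIllusion, meansOther)))
  cand <- if (length(all) > 1L) (head(all, -1) + tail(all, -1)) / 2 else all
  score <- vapply(cand, function(th)
    sum(meansIllusion > th) + sum(meansOther <= th), 0)
  margin <- vapply(cand, function(th) min(abs(all - th)), 0)
  best <- which(score == max(score))
  cand[best][which.max(margin[best])]
}
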