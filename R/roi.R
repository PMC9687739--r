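#' @include AllClasses.R
NULL

#' Per-image dynamic intensity threshold
#'
#' Computes the brightest level of the image, the near-brightest level
#' (brightest minus \code{delta}, floored at 0), and the pixel counts at
#' each. A fixed global threshold fails on mammograms because dense tissue
#' can sit just below the lesion, so the threshold is chosen per image: when
#' the brightest-pixel region is already large enough
#' (\code{countMax >= minRegion}) the brightest level itself is used
#' (branch \code{MAX_SUFFICIENT}); otherwise the threshold is relaxed to the
#' near-brightest level so that near-maximum lesion pixels are not lost
#' (branch \code{NEAR_MAX_EXPANDED}).
#'
#' @param img numeric matrix in [0, 255] with at least one non-zero pixel.
#' @param delta width of the near-maximum band (default 10 of 255).
#' @param minRegion minimal brightest-pixel count for the strict branch
#'   (default 10 pixels).
#' @return a [ThresholdDiagnostics-class] object.
#' @examples
#' img <- matrix(100, 5, 5); img[3, 3] <- 200; img[1, 1:5] <- 195
#' computeDynamicThreshold(img, delta = 10, minRegion = 3)
#' @export
computeDynamicThreshold <- function(img, delta = 10, minRegion = 10) {
  .assertImage(img)
  .stopIfNot(delta >= 0, "delta must be non-negative")
  .stopIfNot(max(img) > 0, "all-zero image: no breast content to threshold")
  maxI <- max(img)
  nearI <- max(maxI - delta, 0)
  countMax <- sum(img == maxI)
  countNear <- sum(img >= nearI & img < maxI)
  if (countMax >= minRegion) {
    chosen <- maxI; rule <- "MAX_SUFFICIENT"
  } else {
    chosen <- nearI; rule <- "NEAR_MAX_EXPANDED"
  }
  new("ThresholdDiagnostics", maxIntensity = maxI, nearMaxIntensity = nearI,
      countMax = as.integer(countMax), countNearMax = as.integer(countNear),
      chosenThreshold = chosen, ruleFired = rule)
}

#' Seed point for region growing
#'
#' The seed is the integer-rounded centroid (floor(x + 0.5) per coordinate)
#' of the brightest-pixel set. If the centroid of a disconnected or concave
#' brightest region happens to fall below the chosen threshold, the seed
#' snaps to the nearest pixel at or above the threshold (Euclidean distance,
#' ties broken in row-major order), so the seed is always growable.
#'
#' @param img the image the diagnostics came from.
#' @param diag a [ThresholdDiagnostics-class] computed from \code{img}.
#' @return integer vector (row, col).
#' @export
findSeed <- function(img, diag) {
  .assertImage(img)
  stopifnot(is(diag, "ThresholdDiagnostics"))
  pts <- which(img == diag@maxIntensity, arr.ind = TRUE)
  .stopIfNot(nrow(pts) >= 1L, "image has no pixel at the recorded maximum")
  seed <- as.integer(floor(colMeans(pts) + 0.5))
  if (img[seed[1L], seed[2L]] >= diag@chosenThreshold) return(seed)
  cand <- which(img >= diag@chosenThreshold, arr.ind = TRUE)
  d2 <- (cand[, 1L] - seed[1L])^2 + (cand[, 2L] - seed[2L])^2
  ord <- order(d2, cand[, 1L], cand[, 2L])
  as.integer(cand[ord[1L], ])
}

#' Seeded region growing
#'
#' Grows the maximal connected region containing the seed whose pixels all
#' have intensity at or above the threshold (flood fill; each pixel is
#' visited once, so termination is guaranteed).
#'
#' @param img numeric matrix in [0, 255].
#' @param seed integer (row, col); its intensity must reach the threshold.
#' @param threshold intensity cutoff.
#' @param connectivity 4 or 8 (default 8: lesion boundaries are irregular and
#'   touch diagonally).
#' @return logical mask of the grown region.
#' @examples
#' img <- matrix(0, 5, 5); img[2:4, 3] <- 255; img[3, 2:4] <- 255
#' sum(regionGrow(img, c(3, 3), 255, connectivity = 4))
#' @export
regionGrow <- function(img, seed, threshold, connectivity = 8L) {
  .assertImage(img)
  seed <- as.integer(seed)
  .stopIfNot(length(seed) == 2L, "seed must be (row, col)")
  .stopIfNot(seed[1L] >= 1L && seed[1L] <= nrow(img) &&
               seed[2L] >= 1L && seed[2L] <= ncol(img), "seed outside image")
  .stopIfNot(img[seed[1L], seed[2L]] >= threshold,
             "seed intensity below threshold")
  .flood_fill(img, seed[1L] - 1L, seed[2L] - 1L, threshold,
              as.integer(connectivity))
}

#' Extract the region of interest
#'
#' The full dynamic-threshold segmentation: compute the per-image threshold
#' diagnostics, place the seed at the brightest-region centroid, grow the
#' connected region at or above the chosen threshold, and mask the input to
#' it. Only the seed's connected component is returned (single-lesion
#' assumption).
#'
#' @inheritParams computeDynamicThreshold
#' @param connectivity 4 or 8.
#' @return an [ROIResult-class]: mask, seed, diagnostics and the ROI image
#'   (input where the mask is set, zero elsewhere).
#' @examples
#' truth <- generatePhantom(phantomSpec(seed = 5, artefactFlags =
#'   c(border_frame = FALSE, text_blob = FALSE, vertical_line = FALSE)))
#' roi <- extractROI(phantomImage(truth))
#' @export
extractROI <- function(img, delta = 10, minRegion = 10, connectivity = 8L) {
  diag <- computeDynamicThreshold(img, delta = delta, minRegion = minRegion)
  seed <- findSeed(img, diag)
  mask <- regionGrow(img, seed, diag@chosenThreshold, connectivity)
  new("ROIResult", mask = mask, seed = seed, diagnostics = diag,
      roiImage = img * mask)
}
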