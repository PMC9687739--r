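#' @include utils.R
NULL

#' Phantom specification
#'
#' Describes a synthetic mammogram-like image: a bright half-elliptical breast
#' flush with the left image edge (mimicking a craniocaudal view), textured
#' dense tissue, a lesion disk that is the brightest structure of the breast,
#' an optional dense-tissue patch slightly below lesion intensity, and three
#' switchable acquisition artefacts (white border frame, text-like blobs,
#' near-vertical white line touching the breast).
#'
#' @slot width,height image size in pixels.
#' @slot breastCenter (row, col) centre of the breast half-ellipse.
#' @slot breastSemiAxes (vertical, horizontal) semi-axes in pixels.
#' @slot breastBaseIntensity mean tissue intensity (8-bit level).
#' @slot tissueTextureSigma standard deviation of the smoothed tissue texture.
#' @slot lesionCenter (row, col) of the lesion disk centre.
#' @slot lesionRadius lesion radius in pixels.
#' @slot lesionIntensity peak lesion intensity; the image maximum inside the
#'   breast. Must exceed \code{breastBaseIntensity + 3 * tissueTextureSigma}.
#' @slot lesionEdgeDrop intensity drop from lesion centre to rim (quadratic
#'   radial profile), so the exact-maximum pixel set is small and the
#'   near-maximum band is exercised.
#' @slot artefactFlags named logical vector with entries \code{border_frame},
#'   \code{text_blob}, \code{vertical_line}.
#' @slot borderThickness thickness of the drawn border frame.
#' @slot densePatch add a dense-tissue patch slightly below lesion intensity.
#' @slot densePatchOffset intensity offset of that patch below the lesion peak.
#' @slot seed RNG seed; identical specs give bit-identical phantoms.
#' @seealso [generatePhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  width = "integer", height = "integer",
  breastCenter = "numeric", breastSemiAxes = "numeric",
  breastBaseIntensity = "numeric", tissueTextureSigma = "numeric",
  lesionCenter = "numeric", lesionRadius = "numeric",
  lesionIntensity = "numeric", lesionEdgeDrop = "numeric",
  artefactFlags = "logical", borderThickness = "integer",
  densePatch = "logical", densePatchOffset = "numeric",
  seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (object@width < 32L || object@height < 32L)
    msgs <- c(msgs, "phantom must be at least 32x32")
  ints <- c(object@breastBaseIntensity, object@lesionIntensity)
  if (any(ints < 0) || any(ints > 255))
    msgs <- c(msgs, "intensities must lie in [0, 255]")
  if (object@lesionIntensity <=
      object@breastBaseIntensity + 3 * object@tissueTextureSigma)
    msgs <- c(msgs, paste("lesionIntensity must exceed breastBaseIntensity +",
                          "3 * tissueTextureSigma (lesion is the breast maximum)"))
  # the whole lesion disk must sit inside the breast half-ellipse
  th <- seq(0, 2 * pi, length.out = 64L)
  rr <- object@lesionCenter[1L] + object@lesionRadius * sin(th)
  cc <- object@lesionCenter[2L] + object@lesionRadius * cos(th)
  a <- object@breastSemiAxes[1L]; b <- object@breastSemiAxes[2L]
  d <- ((rr - object@breastCenter[1L]) / a)^2 +
    ((cc - object@breastCenter[2L]) / b)^2
  if (any(d > 1) || any(cc < object@breastCenter[2L]))
    msgs <- c(msgs, "lesion disk must lie fully inside the breast region")
  if (!all(c("border_frame", "text_blob", "vertical_line") %in%
           names(object@artefactFlags)))
    msgs <- c(msgs, "artefactFlags must name border_frame, text_blob, vertical_line")
  if (length(msgs)) msgs else TRUE
})

#' Phantom ground truth
#'
#' The output of [generatePhantom()]: the synthetic image plus ground-truth
#' breast, lesion and artefact masks, all sharing the image's shape. The
#' lesion mask is contained in the breast mask; the artefact mask intersects
#' the breast only along the vertical-line artefact.
#'
#' @slot image numeric matrix of intensities in [0, 255].
#' @slot breastMask,lesionMask,artefactMask logical matrices.
#' @slot spec the [PhantomSpec-class] that generated the phantom.
#' @exportClass PhantomTruth
setClass("PhantomTruth", representation(
  image = "matrix", breastMask = "matrix", lesionMask = "matrix",
  artefactMask = "matrix", spec = "PhantomSpec"))

setValidity("PhantomTruth", function(object) {
  msgs <- character()
  d <- dim(object@image)
  for (m in c("breastMask", "lesionMask", "artefactMask")) {
    if (!identical(dim(slot(object, m)), d))
      msgs <- c(msgs, sprintf("%s must share the image's shape", m))
  }
  if (any(object@lesionMask & !object@breastMask))
    msgs <- c(msgs, "lesionMask must be contained in breastMask")
  if (length(msgs)) msgs else TRUE
})

#' Enhancement and artefact-removal parameters
#'
#' Parameters of the preprocessing chain. Defaults follow the published
#' configuration: border width 5, Canny thresholds 50/150 (aperture 3),
#' straight-line voting threshold 50, overdraw line width 5, gamma 2.0 with
#' unit gain, CLAHE clip limit 1.0 on an 8x8 tile grid. The line-voting
#' angular step defaults to pi/180 (the coarser pi/50 sometimes quoted for
#' this configuration is supported but looks like a typo).
#'
#' @slot gamma,gain gamma-correction exponent and gain, applied on
#'   [0, 1]-normalised intensities.
#' @slot clipLimit,tileGrid CLAHE contrast clip limit (relative to the uniform
#'   tile histogram) and (rows, cols) tile grid.
#' @slot borderThickness border-mask width in pixels.
#' @slot binarizeMethod "otsu" or "fixed"; \code{fixedThreshold} used when fixed
#'   (and as the fallback for constant images).
#' @slot cannyLow,cannyHigh hysteresis thresholds on the L1 Sobel gradient.
#' @slot angleTol maximal deviation from vertical, degrees.
#' @slot houghVotes minimum accumulator votes for a detected line.
#' @slot thetaStep angular resolution of the voting transform, radians.
#' @slot minLineLength minimum detected segment span, pixels.
#' @slot lineWidth width of the black overdraw.
#' @seealso [enhanceParams()], [preprocessImage()]
#' @exportClass EnhanceParams
setClass("EnhanceParams", representation(
  gamma = "numeric", gain = "numeric",
  clipLimit = "numeric", tileGrid = "integer",
  borderThickness = "integer",
  binarizeMethod = "character", fixedThreshold = "numeric",
  cannyLow = "numeric", cannyHigh = "numeric",
  angleTol = "numeric", houghVotes = "integer",
  thetaStep = "numeric", minLineLength = "numeric", lineWidth = "integer"))

setValidity("EnhanceParams", function(object) {
  msgs <- character()
  if (object@gamma <= 0) msgs <- c(msgs, "gamma must be positive")
  if (object@clipLimit <= 0) msgs <- c(msgs, "clipLimit must be positive")
  if (any(object@tileGrid < 1L)) msgs <- c(msgs, "tileGrid must be positive")
  if (!object@binarizeMethod %in% c("otsu", "fixed"))
    msgs <- c(msgs, "binarizeMethod must be 'otsu' or 'fixed'")
  if (length(msgs)) msgs else TRUE
})

#' Construct enhancement parameters
#'
#' @param gamma,gain,clipLimit,tileGrid,borderThickness,binarizeMethod,fixedThreshold,cannyLow,cannyHigh,angleTol,houghVotes,thetaStep,minLineLength,lineWidth
#'   see [EnhanceParams-class].
#' @return an [EnhanceParams-class] object.
#' @examples
#' enhanceParams(gamma = 1.5)
#' @export
enhanceParams <- function(gamma = 2, gain = 1, clipLimit = 1,
                          tileGrid = c(8L, 8L), borderThickness = 5L,
                          binarizeMethod = "otsu", fixedThreshold = 1,
                          cannyLow = 50, cannyHigh = 150, angleTol = 10,
                          houghVotes = 50L, thetaStep = pi / 180,
                          minLineLength = 50, lineWidth = 5L) {
  new("EnhanceParams", gamma = gamma, gain = gain, clipLimit = clipLimit,
      tileGrid = as.integer(tileGrid), borderThickness = as.integer(borderThickness),
      binarizeMethod = binarizeMethod, fixedThreshold = fixedThreshold,
      cannyLow = cannyLow, cannyHigh = cannyHigh, angleTol = angleTol,
      houghVotes = as.integer(houghVotes), thetaStep = thetaStep,
      minLineLength = minLineLength, lineWidth = as.integer(lineWidth))
}

#' Dynamic-threshold diagnostics
#'
#' Records the per-image statistics behind the dynamic intensity threshold:
#' the brightest level, the near-brightest level (brightest minus delta), how
#' many pixels sit at each, which decision branch fired and the resulting
#' threshold.
#'
#' @slot maxIntensity,nearMaxIntensity brightest and near-brightest levels.
#' @slot countMax pixels exactly at the brightest level.
#' @slot countNearMax pixels in [nearMaxIntensity, maxIntensity).
#' @slot chosenThreshold the selected region-growing threshold; one of the two
#'   candidate levels.
#' @slot ruleFired "MAX_SUFFICIENT" when the brightest-pixel region is large
#'   enough on its own, "NEAR_MAX_EXPANDED" when the threshold was relaxed.
#' @seealso [computeDynamicThreshold()]
#' @exportClass ThresholdDiagnostics
setClass("ThresholdDiagnostics", representation(
  maxIntensity = "numeric", nearMaxIntensity = "numeric",
  countMax = "integer", countNearMax = "integer",
  chosenThreshold = "numeric", ruleFired = "character"))

setValidity("ThresholdDiagnostics", function(object) {
  msgs <- character()
  if (object@nearMaxIntensity > object@maxIntensity)
    msgs <- c(msgs, "nearMaxIntensity must not exceed maxIntensity")
  if (!object@chosenThreshold %in%
      c(object@maxIntensity, object@nearMaxIntensity))
    msgs <- c(msgs, "chosenThreshold must be one of the two candidate levels")
  if (object@countMax < 1L) msgs <- c(msgs, "countMax must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Region-of-interest segmentation result
#'
#' @slot mask logical matrix; one connected component containing the seed.
#' @slot seed integer (row, col) seed point.
#' @slot diagnostics the [ThresholdDiagnostics-class] used.
#' @slot roiImage the input image masked to the ROI (background zero).
#' @seealso [extractROI()]
#' @exportClass ROIResult
setClass("ROIResult", representation(
  mask = "matrix", seed = "integer",
  diagnostics = "ThresholdDiagnostics", roiImage = "matrix"))

setValidity("ROIResult", function(object) {
  msgs <- character()
  if (!identical(dim(object@mask), dim(object@roiImage)))
    msgs <- c(msgs, "mask and roiImage must share a shape")
  if (!object@mask[object@seed[1L], object@seed[2L]])
    msgs <- c(msgs, "seed must lie inside the mask")
  if (length(msgs)) msgs else TRUE
})

#' Image-quality report
#'
#' Mean squared error, its root, peak signal-to-noise ratio (dB; +Inf when the
#' images are identical) and the mean structural-similarity index between a
#' reference and a test image.
#'
#' @slot mse,rmse,psnr,ssim the four metrics.
#' @slot maxLevel dynamic range used for PSNR/SSIM (255 for 8-bit).
#' @seealso [qualityReport()]
#' @exportClass QualityReport
setClass("QualityReport", representation(
  mse = "numeric", rmse = "numeric", psnr = "numeric", ssim = "numeric",
  maxLevel = "numeric"))

setValidity("QualityReport", function(object) {
  msgs <- character()
  if (object@mse < 0) msgs <- c(msgs, "mse must be non-negative")
  if (abs(object@rmse - sqrt(object@mse)) > 1e-8)
    msgs <- c(msgs, "rmse must equal sqrt(mse)")
  if (object@ssim > 1 + 1e-12) msgs <- c(msgs, "ssim must be <= 1")
  if (length(msgs)) msgs else TRUE
})

#' Augmentation set
#'
#' The fixed, ordered list of seven geometric augmentations: horizontal flip,
#' vertical flip, combined flip (equal to a 180-degree rotation), +30 and -30
#' degree rotations, each rotation also combined with a horizontal flip.
#'
#' @slot transforms the seven transform names, in order.
#' @slot rotationFill intensity used outside the rotated support.
#' @slot interpolation "bilinear" or "nearest".
#' @seealso [augmentImage()], [augmentDataset()]
#' @exportClass AugmentSet
setClass("AugmentSet", representation(
  transforms = "character", rotationFill = "numeric",
  interpolation = "character"))

setValidity("AugmentSet", function(object) {
  msgs <- character()
  if (length(object@transforms) != 7L || anyDuplicated(object@transforms))
    msgs <- c(msgs, "exactly seven uniquely named transforms are required")
  if (!object@interpolation %in% c("bilinear", "nearest"))
    msgs <- c(msgs, "interpolation must be 'bilinear' or 'nearest'")
  if (length(msgs)) msgs else TRUE
})

#' Classifier-bank report
#'
#' Train/test accuracy, Matthews correlation coefficient, macro F1 (all in
#' percent) and macro one-vs-rest AUC for every member of the classifier
#' bank, together with the test confusion matrices and the fitted models.
#'
#' @slot metrics data.frame, one row per model, columns
#'   \code{model, train_acc, train_mcc, train_f1, test_acc, test_mcc,
#'   test_f1, auc}.
#' @slot confusions named list of test confusion matrices (true x predicted).
#' @slot models named list of fitted model objects.
#' @slot config the bank configuration list used for training.
#' @seealso [trainBank()]
#' @exportClass EnsembleReport
setClass("EnsembleReport", representation(
  metrics = "data.frame", confusions = "list", models = "list",
  config = "list"))

#' Stacked-ensemble specification
#'
#' The member set of a stacking ensemble, chosen as all bank members whose
#' test accuracy strictly exceeds a threshold, in the bank's declared order.
#' The meta-learner is a multinomial logistic regression over the members'
#' cross-validated class probabilities.
#'
#' @slot accuracyThreshold the percent threshold applied.
#' @slot members selected member names.
#' @slot metaLearner meta-learner identifier (always "logistic").
#' @seealso [selectByAccuracy()], [trainStacked()]
#' @exportClass EnsembleSpec
setClass("EnsembleSpec", representation(
  accuracyThreshold = "numeric", members = "character",
  metaLearner = "character"))

setValidity("EnsembleSpec", function(object) {
  if (length(object@members) < 1L)
    "ensemble member set must be non-empty" else TRUE
})
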