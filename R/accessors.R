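#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor functions for the S4 containers so user code never touches
#' slots directly.
#'
#' @param x a [PhantomTruth-class], [ROIResult-class],
#'   [ThresholdDiagnostics-class], [QualityReport-class],
#'   [EnsembleReport-class] or [EnsembleSpec-class] object, as applicable.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
phantomImage <- function(x) { stopifnot(is(x, "PhantomTruth")); x@image }

#' @rdname accessors
#' @export
breastMask <- function(x) { stopifnot(is(x, "PhantomTruth")); x@breastMask }

#' @rdname accessors
#' @export
lesionMask <- function(x) { stopifnot(is(x, "PhantomTruth")); x@lesionMask }

#' @rdname accessors
#' @export
artefactMask <- function(x) { stopifnot(is(x, "PhantomTruth")); x@artefactMask }

#' @rdname accessors
#' @export
roiMask <- function(x) { stopifnot(is(x, "ROIResult")); x@mask }

#' @rdname accessors
#' @export
roiSeed <- function(x) { stopifnot(is(x, "ROIResult")); x@seed }

#' @rdname accessors
#' @export
roiImage <- function(x) { stopifnot(is(x, "ROIResult")); x@roiImage }

#' @rdname accessors
#' @export
diagnostics <- function(x) { stopifnot(is(x, "ROIResult")); x@diagnostics }

#' @rdname accessors
#' @export
chosenThreshold <- function(x) {
  if (is(x, "ROIResult")) x <- x@diagnostics
  stopifnot(is(x, "ThresholdDiagnostics"))
  x@chosenThreshold
}

#' @rdname accessors
#' @export
ruleFired <- function(x) {
  if (is(x, "ROIResult")) x <- x@diagnostics
  stopifnot(is(x, "ThresholdDiagnostics"))
  x@ruleFired
}

#' @rdname accessors
#' @export
bankMetrics <- function(x) { stopifnot(is(x, "EnsembleReport")); x@metrics }

#' @rdname accessors
#' @export
bankConfusions <- function(x) { stopifnot(is(x, "EnsembleReport")); x@confusions }

#' @rdname accessors
#' @export
selectedMembers <- function(x) { stopifnot(is(x, "EnsembleSpec")); x@members }

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomTruth %dx%d | breast %d px | lesion %d px | artefacts %d px\n",
              d[1L], d[2L], sum(object@breastMask), sum(object@lesionMask),
              sum(object@artefactMask)))
})

setMethod("show", "ThresholdDiagnostics", function(object) {
  cat(sprintf(paste0("ThresholdDiagnostics: max %g (n=%d), near-max %g (n=%d) ",
                     "-> threshold %g [%s]\n"),
              object@maxIntensity, object@countMax, object@nearMaxIntensity,
              object@countNearMax, object@chosenThreshold, object@ruleFired))
})

setMethod("show", "ROIResult", function(object) {
  cat(sprintf("ROIResult: %d px at seed (%d, %d), threshold %g [%s]\n",
              sum(object@mask), object@seed[1L], object@seed[2L],
              object@diagnostics@chosenThreshold, object@diagnostics@ruleFired))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: MSE %.4g | RMSE %.4g | PSNR %.4g dB | SSIM %.4f\n",
              object@mse, object@rmse, object@psnr, object@ssim))
})

setMethod("show", "EnsembleReport", function(object) {
  cat(sprintf("EnsembleReport: %d model(s)\n", nrow(object@metrics)))
  print(object@metrics, digits = 4)
})

setMethod("show", "EnsembleSpec", function(object) {
  cat(sprintf("EnsembleSpec (> %g%%): %s -> %s meta-learner\n",
              object@accuracyThreshold, paste(object@members, collapse = "+"),
              object@metaLearner))
})
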