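#' @include AllClasses.R
NULL

#' Mean squared error between two images
#'
#' Mean of squared pixel differences over all pixels. Zero means the images
#' are identical; values above about 0.5 flag visible degradation on the
#' 8-bit scale.
#'
#' @param ref,test numeric matrices of identical shape.
#' @return the MSE, in squared intensity units.
#' @examples
#' imageMSE(matrix(0, 2, 2), matrix(2, 2, 2))  # 4
#' @export
imageMSE <- function(ref, test) {
  .assertImage(ref, "ref"); .assertImage(test, "test"); .sameShape(ref, test)
  mean((ref - test)^2)
}

#' Root mean squared error between two images
#'
#' @inheritParams imageMSE
#' @return \code{sqrt(imageMSE(ref, test))}, in intensity units.
#' @export
imageRMSE <- function(ref, test) sqrt(imageMSE(ref, test))

#' Peak signal-to-noise ratio
#'
#' \code{20 * log10(maxLevel / rmse)} in decibels. Identical images return
#' \code{Inf} (documented sentinel). For 8-bit images, values between 30 and
#' 50 dB are conventionally acceptable.
#'
#' @inheritParams imageMSE
#' @param maxLevel the maximal representable intensity (255 for 8-bit).
#' @return PSNR in dB.
#' @export
imagePSNR <- function(ref, test, maxLevel = 255) {
  .stopIfNot(maxLevel > 0, "maxLevel must be positive")
  m <- imageMSE(ref, test)
  if (m == 0) return(Inf)
  20 * log10(maxLevel / sqrt(m))
}

#' Mean structural-similarity index (SSIM)
#'
#' Windowed structural similarity with the standard Gaussian window (11x11,
#' sigma 1.5) and stabilisers \code{c1 = (0.01 maxLevel)^2},
#' \code{c2 = (0.03 maxLevel)^2}, averaged over all positions where the full
#' window fits. Values lie in [-1, 1]; identical images give exactly 1.
#'
#' @inheritParams imagePSNR
#' @param window odd window side length; must not exceed either dimension.
#' @param sigma Gaussian window standard deviation.
#' @param c1,c2 stabilising constants.
#' @return the mean SSIM.
#' @export
imageSSIM <- function(ref, test, maxLevel = 255, window = 11L, sigma = 1.5,
                      c1 = (0.01 * maxLevel)^2, c2 = (0.03 * maxLevel)^2) {
  .assertImage(ref, "ref"); .assertImage(test, "test"); .sameShape(ref, test)
  window <- as.integer(window)
  .stopIfNot(window %% 2L == 1L, "window must be odd")
  .stopIfNot(window <= min(dim(ref)), "window must not exceed the image")
  k1 <- .gaussianKernel1d(sigma, radius = (window - 1L) %/% 2L)
  kern <- outer(k1, k1)
  f <- function(x) .conv2(x, kern, pad = "value", value = 0)
  mux <- f(ref); muy <- f(test)
  sxx <- f(ref^2) - mux^2
  syy <- f(test^2) - muy^2
  sxy <- f(ref * test) - mux * muy
  ssimMap <- ((2 * mux * muy + c1) * (2 * sxy + c2)) /
    ((mux^2 + muy^2 + c1) * (sxx + syy + c2))
  m <- (window - 1L) %/% 2L
  rows <- (m + 1L):(nrow(ref) - m)
  cols <- (m + 1L):(ncol(ref) - m)
  mean(ssimMap[rows, cols])
}

#' Full image-quality report
#'
#' Computes MSE, RMSE, PSNR and SSIM between a reference (e.g.
#' artefact-removed) and a test (e.g. enhanced) image and returns them as a
#' [QualityReport-class].
#'
#' @inheritParams imageSSIM
#' @return a [QualityReport-class] object.
#' @examples
#' a <- matrix(runif(64, 0, 255), 16, 4)
#' \dontrun{qualityReport(a, a)}
#' @export
qualityReport <- function(ref, test, maxLevel = 255, window = 11L) {
  m <- imageMSE(ref, test)
  new("QualityReport", mse = m, rmse = sqrt(m),
      psnr = imagePSNR(ref, test, maxLevel),
      ssim = imageSSIM(ref, test, maxLevel, window = window),
      maxLevel = maxLevel)
}

#' Quality gate
#'
#' Flags a processed image whose error exceeds the noise-free bound or whose
#' PSNR falls outside the conventional acceptance band for 8-bit images.
#'
#' @param report a [QualityReport-class].
#' @param mseMax maximal acceptable MSE (default 0.5 on the 8-bit scale,
#'   rescale for other ranges).
#' @param psnrRange acceptable PSNR interval in dB (default c(30, 50);
#'   \code{Inf} from identical images always passes).
#' @return TRUE when the image should be flagged.
#' @export
qualityGate <- function(report, mseMax = 0.5, psnrRange = c(30, 50)) {
  stopifnot(is(report, "QualityReport"))
  if (report@mse > mseMax) return(TRUE)
  if (is.infinite(report@psnr)) return(FALSE)   # identical images always pass
  report@psnr < psnrRange[1L] || report@psnr > psnrRange[2L]
}
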