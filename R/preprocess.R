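#' @include AllClasses.R
NULL

#' Zero out a border frame
#'
#' Sets every pixel within \code{thickness} of any image edge to zero,
#' removing white frame artefacts. Idempotent; the interior is untouched.
#'
#' @param img numeric matrix in [0, 255].
#' @param thickness border width in pixels; must be below half the smaller
#'   image dimension.
#' @return the masked image.
#' @examples
#' img <- matrix(255, 10, 10)
#' applyBorderMask(img, 2)[1, 1]
#' @export
applyBorderMask <- function(img, thickness = 5L) {
  .assertImage(img)
  thickness <- as.integer(thickness)
  .stopIfNot(thickness >= 0L, "thickness must be non-negative")
  .stopIfNot(thickness < min(dim(img)) / 2,
             "thickness must be below half the smaller image dimension")
  if (thickness == 0L) return(img)
  nr <- nrow(img); nc <- ncol(img)
  img[c(seq_len(thickness), (nr - thickness + 1L):nr), ] <- 0
  img[, c(seq_len(thickness), (nc - thickness + 1L):nc)] <- 0
  img
}

#' Binarise an image
#'
#' Thresholds an image into a logical mask (\code{TRUE} where intensity is at
#' or above the threshold). With \code{method = "otsu"} the threshold is the
#' smallest level maximising the between-class variance of the 256-bin
#' histogram; a constant image falls back to \code{fixedThreshold} with a
#' message.
#'
#' @param img numeric matrix in [0, 255].
#' @param method "otsu" or "fixed".
#' @param fixedThreshold threshold used when \code{method = "fixed"} (and as
#'   the constant-image fallback).
#' @return logical matrix; attribute \code{threshold} records the level used.
#' @examples
#' m <- binarize(matrix(c(10, 10, 200, 200), 2), method = "otsu")
#' attr(m, "threshold")
#' @export
binarize <- function(img, method = c("otsu", "fixed"), fixedThreshold = 1) {
  .assertImage(img)
  method <- match.arg(method)
  if (method == "otsu") {
    lev <- floor(img)
    if (min(lev) == max(lev)) {
      message("constant image: Otsu undefined, falling back to fixed threshold")
      thr <- fixedThreshold
    } else {
      h <- tabulate(lev + 1L, nbins = 256L)
      n <- sum(h)
      levels <- 0:255
      cw <- cumsum(h)                      # pixels at level < t for t = 1..256
      cm <- cumsum(h * levels)
      total <- cm[256L]
      # candidate thresholds t: class0 = {level < t}, class1 = {level >= t}
      w0 <- cw[1:255]; w1 <- n - w0
      valid <- w0 > 0 & w1 > 0
      mu0 <- cm[1:255] / pmax(w0, 1)
      mu1 <- (total - cm[1:255]) / pmax(w1, 1)
      sb <- w0 * w1 * (mu0 - mu1)^2
      sb[!valid] <- -Inf
      thr <- which.max(sb)                 # smallest maximiser, level t
    }
  } else {
    thr <- fixedThreshold
  }
  out <- img >= thr
  attr(out, "threshold") <- thr
  out
}

#' Keep the largest connected component, holes filled
#'
#' Labels the mask's connected components (8-connectivity by default), keeps
#' the one with the largest pixel area and fills its interior holes, i.e. the
#' filled region enclosed by the outer contour. On a mammogram this isolates
#' the breast, the largest bright structure. Area ties are broken towards the
#' component whose top-left-most pixel comes first in row-major order.
#'
#' @param mask logical matrix with at least one \code{TRUE} pixel.
#' @param connectivity 4 or 8.
#' @return logical matrix containing a single filled component.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE; m[7, 7] <- TRUE
#' sum(largestComponentMask(m))
#' @export
largestComponentMask <- function(mask, connectivity = 8L) {
  .assertMask(mask)
  .stopIfNot(any(mask), "mask has no foreground pixels")
  lab <- .cc_label(mask, as.integer(connectivity))
  areas <- tabulate(lab[lab > 0L])
  # labels are assigned in row-major first-encounter order, so which.max's
  # first-maximum rule is exactly the documented tie-break
  best <- which.max(areas)
  .fillHoles(lab == best)
}

# Sobel gradients, L1 magnitude (the OpenCV default for aperture 3),
# 4-direction non-maximum suppression and hysteresis by connected components.
.cannyEdges <- function(img, lo, hi) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dcol
  sy <- t(sx)                                                # d/drow
  gx <- .conv2(img, sx, pad = "replicate")
  gy <- .conv2(img, sy, pad = "replicate")
  mag <- abs(gx) + abs(gy)
  # quantise gradient direction into 4 bins and suppress non-maxima
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  bin <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4L
  big <- .padMatrix(mag, 1L)
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(dr, dc)
    big[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  keep <- matrix(FALSE, nr, nc)
  # bin 0: gradient ~ horizontal -> compare left/right neighbours
  n1 <- list(shift(0L, -1L), shift(-1L, -1L), shift(-1L, 0L), shift(-1L, 1L))
  n2 <- list(shift(0L, 1L), shift(1L, 1L), shift(1L, 0L), shift(1L, -1L))
  for (b in 0:3) {
    sel <- bin == b
    keep[sel] <- mag[sel] >= n1[[b + 1L]][sel] & mag[sel] >= n2[[b + 1L]][sel]
  }
  strong <- keep & mag >= hi
  weak <- keep & mag >= lo
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- .cc_label(weak, 8L)
  good <- unique(lab[strong])
  weak & matrix(lab %in% good, nr, nc)
}

#' Detect and erase near-vertical bright lines
#'
#' Finds near-vertical straight lines (within \code{angleTol} degrees of
#' vertical) with Canny edge detection followed by a straight-line voting
#' (Hough) transform, then overdraws each detected segment with black at
#' \code{lineWidth}, removing line artefacts attached to the breast. Images
#' without such lines are returned unchanged.
#'
#' @param img numeric matrix in [0, 255].
#' @param cannyLow,cannyHigh hysteresis thresholds on the L1 Sobel magnitude.
#' @param angleTol maximal deviation from vertical, degrees.
#' @param minLineLength minimal segment span (pixels) for a detection.
#' @param lineWidth width of the black overdraw stroke.
#' @param houghVotes minimal accumulator votes for a candidate line.
#' @param thetaStep angular resolution of the voting transform (radians).
#' @return the image with detected vertical segments erased; attribute
#'   \code{lines} holds a data.frame of detections (theta, rho, votes, span).
#' @export
removeVerticalLines <- function(img, cannyLow = 50, cannyHigh = 150,
                                angleTol = 10, minLineLength = 50,
                                lineWidth = 5L, houghVotes = 50L,
                                thetaStep = pi / 180) {
  .assertImage(img)
  edges <- .cannyEdges(img, cannyLow, cannyHigh)
  det <- data.frame(theta = numeric(), rho = numeric(),
                    votes = integer(), span = numeric())
  if (!any(edges)) {
    attr(img, "lines") <- det
    return(img)
  }
  pts <- which(edges, arr.ind = TRUE)
  x <- pts[, 2L] - 1            # col, 0-based
  y <- pts[, 1L] - 1            # row, 0-based
  # a vertical line has a horizontal normal: theta ~ 0 in x cos + y sin = rho
  thetas <- seq(-angleTol * pi / 180, angleTol * pi / 180, by = thetaStep)
  radius <- max(1L, as.integer(lineWidth) %/% 2L)
  nr <- nrow(img); nc <- ncol(img)
  X <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)
  Y <- matrix(0:(nr - 1L), nr, nc)
  for (th in thetas) {
    rho <- round(x * cos(th) + y * sin(th))
    tab <- table(rho)
    hits <- as.numeric(names(tab)[tab >= houghVotes])
    for (r0 in hits) {
      on <- abs(x * cos(th) + y * sin(th) - r0) <= 1
      tpos <- -x[on] * sin(th) + y[on] * cos(th)
      span <- diff(range(tpos))
      if (span < minLineLength) next
      det <- rbind(det, data.frame(theta = th, rho = r0,
                                   votes = as.integer(tab[as.character(r0)]),
                                   span = span))
      d <- abs(X * cos(th) + Y * sin(th) - r0)
      tAll <- -X * sin(th) + Y * cos(th)
      img[d <= radius & tAll >= min(tpos) - radius & tAll <= max(tpos) + radius] <- 0
    }
  }
  attr(img, "lines") <- det
  img
}

#' Gamma correction
#'
#' Power-law intensity mapping \code{Vout = gain * Vin^gamma} applied on
#' [0, 1]-normalised intensities and rescaled to [0, 255]. Monotone in the
#' input; gamma < 1 brightens, gamma > 1 darkens, gamma = 1 with unit gain is
#' the identity.
#'
#' @param img numeric matrix in [0, 255].
#' @param gamma positive exponent (published default 2.0).
#' @param gain multiplicative gain on the normalised scale (default 1).
#' @return the corrected image, clipped to [0, 255].
#' @examples
#' gammaCorrect(matrix(127.5, 1, 1), gamma = 2)  # 0.5^2 * 255
#' @export
gammaCorrect <- function(img, gamma = 2, gain = 1) {
  .assertImage(img)
  .stopIfNot(gamma > 0, "gamma must be positive")
  .clip255(gain * (img / 255)^gamma * 255)
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Tile-wise histogram equalisation with a clipped histogram (excess mass
#' redistributed uniformly) and bilinear interpolation between neighbouring
#' tile mappings, removing tile-boundary seams. The clip limit is expressed
#' relative to the uniform tile histogram, as in the usual 8-bit
#' implementation: the per-bin ceiling is \code{clipLimit * tileArea / 256}.
#' Constant images map to constant images.
#'
#' @param img numeric matrix in [0, 255].
#' @param clipLimit relative contrast clip limit (published default 1.0).
#' @param tileGrid (rows, cols) tile grid (published default c(8, 8)).
#' @return the equalised image, intensities in [0, 255].
#' @export
clahe <- function(img, clipLimit = 1, tileGrid = c(8L, 8L)) {
  .assertImage(img)
  .stopIfNot(clipLimit > 0, "clipLimit must be positive")
  tg <- as.integer(tileGrid)
  nr <- nrow(img); nc <- ncol(img)
  .stopIfNot(all(tg >= 1L), "tileGrid must be positive")
  .stopIfNot(tg[1L] <= nr && tg[2L] <= nc,
             "tileGrid must not exceed the image size")
  lev <- pmin(pmax(floor(img), 0), 255)

  th <- ceiling(nr / tg[1L]); tw <- ceiling(nc / tg[2L])
  # pad by edge replication so tiles are equal-sized
  ri <- c(seq_len(nr), rep(nr, th * tg[1L] - nr))
  ci <- c(seq_len(nc), rep(nc, tw * tg[2L] - nc))
  big <- lev[ri, ci, drop = FALSE]
  area <- th * tw
  clip <- max(1, clipLimit * area / 256)

  ntiles <- tg[1L] * tg[2L]
  lut <- matrix(0, ntiles, 256L)          # tile index varies fastest by row
  for (tj in seq_len(tg[2L])) {
    for (ti in seq_len(tg[1L])) {
      tile <- big[((ti - 1L) * th + 1L):(ti * th),
                  ((tj - 1L) * tw + 1L):(tj * tw)]
      h <- tabulate(tile + 1L, nbins = 256L)
      excess <- sum(pmax(h - clip, 0))
      h <- pmin(h, clip) + excess / 256
      lut[(tj - 1L) * tg[1L] + ti, ] <- round(cumsum(h) / area * 255)
    }
  }

  # bilinear interpolation between the four surrounding tile mappings
  tileOfRow <- (seq_len(nr) - 0.5) / th + 0.5   # fractional tile coordinate
  tileOfCol <- (seq_len(nc) - 0.5) / tw + 0.5
  i0 <- pmin(pmax(floor(tileOfRow), 1L), tg[1L])
  i1 <- pmin(i0 + 1L, tg[1L])
  wy <- pmin(pmax(tileOfRow - i0, 0), 1)
  j0 <- pmin(pmax(floor(tileOfCol), 1L), tg[2L])
  j1 <- pmin(j0 + 1L, tg[2L])
  wx <- pmin(pmax(tileOfCol - j0, 0), 1)

  I0 <- matrix(i0, nr, nc); I1 <- matrix(i1, nr, nc)
  J0 <- matrix(j0, nr, nc, byrow = TRUE); J1 <- matrix(j1, nr, nc, byrow = TRUE)
  WY <- matrix(wy, nr, nc); WX <- matrix(wx, nr, nc, byrow = TRUE)
  V <- lev + 1L
  g <- function(I, J) matrix(lut[cbind(as.vector((J - 1L) * tg[1L] + I),
                                       as.vector(V))], nr, nc)
  out <- (1 - WY) * (1 - WX) * g(I0, J0) + (1 - WY) * WX * g(I0, J1) +
    WY * (1 - WX) * g(I1, J0) + WY * WX * g(I1, J1)
  .clip255(out)
}

#' Full preprocessing chain
#'
#' Runs the artefact-removal and enhancement stages in their fixed order:
#' border mask, binarisation, largest-component (breast) isolation, mask
#' application, vertical-line removal, gamma correction, CLAHE. Parameters
#' come from an [EnhanceParams-class]; the defaults are the published
#' configuration.
#'
#' @param img numeric matrix in [0, 255].
#' @param params an [EnhanceParams-class] (default [enhanceParams()]).
#' @param saveIntermediates logical; when TRUE the per-stage images are
#'   attached as attribute \code{intermediates}.
#' @return the preprocessed image; attribute \code{breastMask} holds the
#'   isolated breast mask.
#' @examples
#' truth <- generatePhantom(phantomSpec(seed = 2))
#' pre <- preprocessImage(phantomImage(truth))
#' @export
preprocessImage <- function(img, params = enhanceParams(),
                            saveIntermediates = FALSE) {
  .assertImage(img)
  validObject(params)
  steps <- list()
  x <- applyBorderMask(img, params@borderThickness)
  if (saveIntermediates) steps$border_masked <- x
  bin <- binarize(x, method = params@binarizeMethod,
                  fixedThreshold = params@fixedThreshold)
  mask <- largestComponentMask(bin)
  x <- x * mask
  if (saveIntermediates) steps$breast_isolated <- x
  x <- removeVerticalLines(x, cannyLow = params@cannyLow,
                           cannyHigh = params@cannyHigh,
                           angleTol = params@angleTol,
                           minLineLength = params@minLineLength,
                           lineWidth = params@lineWidth,
                           houghVotes = params@houghVotes,
                           thetaStep = params@thetaStep)
  lines <- attr(x, "lines")
  attr(x, "lines") <- NULL
  if (saveIntermediates) steps$line_removed <- x
  x <- gammaCorrect(x, gamma = params@gamma, gain = params@gain)
  if (saveIntermediates) steps$gamma_corrected <- x
  # the clipped-histogram mapping lifts level 0 slightly; remember the black
  # support (background and overdrawn lines) and re-impose it afterwards
  zeroSupport <- x == 0
  x <- clahe(x, clipLimit = params@clipLimit, tileGrid = params@tileGrid)
  x[zeroSupport] <- 0
  x <- x * mask
  attr(x, "breastMask") <- mask
  attr(x, "lines") <- lines
  if (saveIntermediates) attr(x, "intermediates") <- steps
  x
}
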