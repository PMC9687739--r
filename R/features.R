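#' @include AllClasses.R roi.R
NULL

# Marching-squares contour length of a binary mask at level 0.5, applied to
# a lightly smoothed copy of the mask so the level crossings interpolate to
# sub-pixel positions. On raw 0/1 data every crossing sits at an edge
# midpoint and the contour hugs the pixel staircase, overestimating smooth
# boundaries by several percent; the smoothed field removes that bias (a
# rasterised disk's perimeter comes out within ~1% of 2*pi*r). Degenerate
# masks whose smoothed field never crosses the level fall back to the
# binary-midpoint contour.
.msPerimeter <- function(mask) {
  f <- .gaussianBlur(.padMatrix(mask * 1, 3L), sigma = 0.8, radius = 3L)
  p <- .msLevelLength(f, 0.5)
  if (p > 0) p else .msPerimeterBinary(mask)
}

# Binary-midpoint marching squares: segments join edge midpoints, lengths
# sqrt(2)/2 (corner cut), 1 (straight crossing) or sqrt(2) (double diagonal).
# Cell code = a + 2b + 4c + 8d for corners a=(r,c) b=(r,c+1) c=(r+1,c)
# d=(r+1,c+1).
.msPerimeterBinary <- function(mask) {
  s2 <- sqrt(2) / 2
  lens <- c(0, s2, s2, 1, s2, 1, 2 * s2, s2,
            s2, 2 * s2, 1, s2, 1, s2, s2, 0)
  m <- .padMatrix(mask * 1, 1L)
  nr <- nrow(m); nc <- ncol(m)
  a <- m[1:(nr - 1), 1:(nc - 1)]
  b <- m[1:(nr - 1), 2:nc]
  cc <- m[2:nr, 1:(nc - 1)]
  d <- m[2:nr, 2:nc]
  code <- a + 2 * b + 4 * cc + 8 * d
  sum(lens[code + 1])
}

# Total iso-contour length of field f at `level` by per-cell marching
# squares with linearly interpolated edge crossings.
.msLevelLength <- function(f, level) {
  nr <- nrow(f); nc <- ncol(f)
  f00 <- f[1:(nr - 1), 1:(nc - 1)]   # top-left a
  f01 <- f[1:(nr - 1), 2:nc]         # top-right b
  f10 <- f[2:nr, 1:(nc - 1)]         # bottom-left c
  f11 <- f[2:nr, 2:nc]               # bottom-right d
  a <- f00 > level; b <- f01 > level
  cc <- f10 > level; d <- f11 > level
  code <- a + 2 * b + 4 * cc + 8 * d
  frac <- function(u, v) {
    t <- (level - u) / (v - u)
    t[!is.finite(t)] <- 0.5
    pmin(pmax(t, 0), 1)
  }
  # crossing coordinates (row, col) on each cell edge, relative to the cell
  topC <- frac(f00, f01);  topR <- 0;            # (0, topC)
  botC <- frac(f10, f11)                          # (1, botC)
  lefR <- frac(f00, f10)                          # (lefR, 0)
  rigR <- frac(f01, f11)                          # (rigR, 1)
  seg <- function(r1, c1, r2, c2, sel)
    sum(sqrt((r1 - r2)^2 + (c1 - c2)^2)[sel])
  total <- 0
  Z <- matrix(0, nr - 1, nc - 1); O <- Z + 1
  # case -> segment endpoints (edges: top/bottom/left/right)
  total <- total + seg(Z, topC, lefR, Z, code %in% c(1, 14))        # top-left
  total <- total + seg(Z, topC, rigR, O, code %in% c(2, 13))        # top-right
  total <- total + seg(lefR, Z, rigR, O, code %in% c(3, 12))        # left-right
  total <- total + seg(lefR, Z, O, botC, code %in% c(4, 11))        # left-bottom
  total <- total + seg(Z, topC, O, botC, code %in% c(5, 10))        # top-bottom
  total <- total + seg(rigR, O, O, botC, code %in% c(7, 8))         # right-bottom
  # ambiguous saddles: two opposite corner cuts
  total <- total + seg(Z, topC, rigR, O, code == 6) +
    seg(lefR, Z, O, botC, code == 6)
  total <- total + seg(Z, topC, lefR, Z, code == 9) +
    seg(rigR, O, O, botC, code == 9)
  total
}

# Pixel count of the filled convex hull of the mask (pixels whose centres lie
# inside or on the hull of the mask pixel centres).
.convexArea <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n <= 2L) return(n)
  hull <- grDevices::chull(pts[, 2L], pts[, 1L])   # x = col, y = row
  hx <- pts[hull, 2L]; hy <- pts[hull, 1L]
  nh <- length(hull)
  if (nh <= 2L) return(n)
  rs <- range(pts[, 1L]); cs <- range(pts[, 2L])
  gr <- matrix(rs[1L]:rs[2L], diff(rs) + 1L, diff(cs) + 1L)
  gc <- matrix(cs[1L]:cs[2L], diff(rs) + 1L, diff(cs) + 1L, byrow = TRUE)
  inside <- matrix(TRUE, nrow(gr), ncol(gr))
  # orient the hull once (shoelace sign), then test each edge half-plane
  jn <- c(seq_len(nh)[-1L], 1L)
  orient <- sign(sum(hx * hy[jn] - hx[jn] * hy))
  if (orient == 0) orient <- 1
  for (i in seq_len(nh)) {
    j <- jn[i]
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    crossv <- ex * (gr - hy[i]) - ey * (gc - hx[i])
    inside <- inside & (orient * crossv >= -1e-9)
  }
  sum(inside)
}

# GLCM entropy: symmetric co-occurrence of horizontally adjacent
# (distance 1, angle 0) quantised levels, both pixels inside the mask.
.glcmEntropy <- function(img, mask, levels = 64L) {
  q <- pmin(floor(img / 256 * levels), levels - 1L)
  left <- mask[, -ncol(mask), drop = FALSE] & mask[, -1L, drop = FALSE]
  if (!any(left)) return(0)
  qi <- q[, -ncol(q), drop = FALSE][left]
  qj <- q[, -1L, drop = FALSE][left]
  counts <- tabulate(qi * levels + qj + 1L, nbins = levels * levels)
  counts <- counts + tabulate(qj * levels + qi + 1L, nbins = levels * levels)
  g <- counts[counts > 0] / sum(counts)
  -sum(g * log2(g))
}

#' Compute the sixteen lesion descriptors
#'
#' Shape, intensity and texture descriptors of a segmented lesion:
#' \itemize{
#'   \item \code{area}: mask pixel count; \code{filled_area}: the same with
#'     interior holes filled; \code{convex_area}: pixel count of the filled
#'     convex hull.
#'   \item \code{perimeter_area_ratio}: marching-squares contour length over
#'     area; \code{circularity}: \code{4*pi*A/P^2} (1 for a perfect disk);
#'     \code{solidity}: \code{A / convex_area}; \code{extent}: \code{A} over
#'     the bounding-box area; \code{equivalent_diameter}: diameter of the
#'     equal-area circle \code{sqrt(4A/pi)} (an equal-perimeter variant
#'     \code{P/pi} is available via \code{equivalentDiameter}).
#'   \item \code{major_axis_length}, \code{minor_axis_length}: axes of the
#'     ellipse sharing the mask's second-order central moments.
#'   \item \code{mean_intensity}, \code{std_intensity}, \code{skewness},
#'     \code{kurtosis} (non-excess: a Gaussian gives 3): moments of the
#'     mask-pixel intensities (population denominators); a single-pixel or
#'     constant region has std/skewness/kurtosis 0.
#'   \item \code{shannon_entropy}: bits over the 256-bin intensity histogram
#'     of mask pixels; \code{glcm_entropy}: entropy of the symmetric,
#'     normalised grey-level co-occurrence matrix (distance 1, angle 0,
#'     \code{glcmLevels} quantised levels, mask-interior pairs only).
#' }
#' Background pixels never influence any descriptor.
#'
#' @param roi an [ROIResult-class], or a logical mask (then \code{img} must
#'   be given).
#' @param img image used for intensity descriptors when \code{roi} is a mask.
#' @param glcmLevels quantisation levels for the co-occurrence matrix.
#' @param equivalentDiameter "area" (standard, default) or "perimeter".
#' @return named numeric vector of the 16 descriptors, in the order of
#'   [mammocadFeatureNames()].
#' @examples
#' truth <- generatePhantom(phantomSpec(seed = 5, artefactFlags =
#'   c(border_frame = FALSE, text_blob = FALSE, vertical_line = FALSE)))
#' roi <- extractROI(phantomImage(truth))
#' computeFeatures(roi)["circularity"]
#' @export
computeFeatures <- function(roi, img = NULL, glcmLevels = 64L,
                            equivalentDiameter = c("area", "perimeter")) {
  equivalentDiameter <- match.arg(equivalentDiameter)
  if (is(roi, "ROIResult")) {
    mask <- roi@mask
    img <- roi@roiImage
  } else {
    mask <- roi
    .assertMask(mask)
    .stopIfNot(!is.null(img), "an image is required when roi is a mask")
  }
  .stopIfNot(any(mask), "empty mask: no region to describe")

  area <- sum(mask)
  per <- .msPerimeter(mask)
  convex <- .convexArea(mask)
  filled <- sum(.fillHoles(mask))
  pts <- which(mask, arr.ind = TRUE)
  bbox <- (diff(range(pts[, 1L])) + 1L) * (diff(range(pts[, 2L])) + 1L)

  if (area > 1L) {
    mr <- mean(pts[, 1L]); mc <- mean(pts[, 2L])
    dr <- pts[, 1L] - mr; dc <- pts[, 2L] - mc
    covm <- matrix(c(mean(dr^2), mean(dr * dc), mean(dr * dc), mean(dc^2)), 2L)
    ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
    major <- 4 * sqrt(max(ev[1L], 0))
    minor <- 4 * sqrt(max(ev[2L], 0))
  } else {
    major <- minor <- 0
  }

  vals <- img[mask]
  mu <- mean(vals)
  s2 <- mean((vals - mu)^2)
  sdev <- sqrt(s2)
  if (sdev > 0) {
    skew <- mean((vals - mu)^3) / sdev^3
    kurt <- mean((vals - mu)^4) / sdev^4
  } else {
    skew <- 0; kurt <- 0
  }
  h <- tabulate(pmin(pmax(floor(vals), 0), 255) + 1L, nbins = 256L)
  p <- h[h > 0] / length(vals)
  shannon <- -sum(p * log2(p))

  eqd <- if (equivalentDiameter == "area") sqrt(4 * area / pi) else per / pi

  out <- c(area = area,
           perimeter_area_ratio = per / area,
           convex_area = convex,
           solidity = area / convex,
           circularity = 4 * pi * area / per^2,
           equivalent_diameter = eqd,
           extent = area / bbox,
           filled_area = filled,
           major_axis_length = major,
           minor_axis_length = minor,
           mean_intensity = mu,
           std_intensity = sdev,
           shannon_entropy = shannon,
           glcm_entropy = .glcmEntropy(img, mask, glcmLevels),
           skewness = skew,
           kurtosis = kurt)
  out[mammocadFeatureNames()]
}

#' Assemble the labelled feature table
#'
#' One row of the 16 descriptors per ROI, plus integer class codes (string
#' labels BC/BM/MC/MM are mapped to 0/1/2/3). ROIs whose descriptor
#' computation fails are skipped with a warning naming the reason.
#'
#' @param rois list of [ROIResult-class] objects.
#' @param labels aligned class labels (integer codes or BC/BM/MC/MM strings).
#' @param imageIds optional provenance identifiers (default the list index).
#' @param ... passed on to [computeFeatures()].
#' @return data.frame with \code{image_id}, the 16 descriptor columns and
#'   \code{label}.
#' @export
buildFeatureTable <- function(rois, labels, imageIds = NULL, ...) {
  .stopIfNot(length(rois) == length(labels),
             "rois and labels must be aligned")
  if (is.null(imageIds)) imageIds <- as.character(seq_along(rois))
  codes <- encodeClassLabels(labels)
  rows <- vector("list", length(rois))
  keep <- logical(length(rois))
  for (i in seq_along(rois)) {
    fv <- tryCatch(computeFeatures(rois[[i]], ...), error = function(e) e)
    if (inherits(fv, "error")) {
      warning(sprintf("skipping ROI %s: %s", imageIds[i], conditionMessage(fv)),
              call. = FALSE)
    } else {
      rows[[i]] <- fv
      keep[i] <- TRUE
    }
  }
  feats <- do.call(rbind, rows[keep])
  out <- data.frame(image_id = imageIds[keep])
  if (!is.null(feats)) out <- cbind(out, as.data.frame(feats))
  else for (nm in mammocadFeatureNames()) out[[nm]] <- numeric(0)
  out$label <- codes[keep]
  rownames(out) <- NULL
  out
}

#' Encode class labels as integer codes
#'
#' Maps the four class names to their integer codes (BC = 0, BM = 1, MC = 2,
#' MM = 3); numeric labels are passed through as integers.
#'
#' @param labels character or numeric labels.
#' @return integer codes.
#' @export
encodeClassLabels <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels))
  map <- c(BC = 0L, BM = 1L, MC = 2L, MM = 3L)
  lab <- as.character(labels)
  .stopIfNot(all(lab %in% names(map)),
             "string labels must be among BC, BM, MC, MM")
  unname(map[lab])
}

.featureColumns <- function(table) {
  setdiff(names(table), c("label", "image_id"))
}

#' Min-max normalisation of a feature table
#'
#' Rescales every feature column affinely so its training minimum maps to 0
#' and maximum to 1; constant columns map to 0. The fitted ranges are
#' returned so held-out rows can be transformed with
#' [applyNormalization()] — such rows may leave [0, 1] and are deliberately
#' not clipped.
#'
#' @param table feature data.frame (a \code{label} column, if present, is
#'   left untouched).
#' @return list with \code{table} (normalised) and \code{ranges} (data.frame
#'   of feature, min, max).
#' @examples
#' minmaxNormalize(data.frame(a = c(2, 4, 6), label = 0:2))$table$a
#' @export
minmaxNormalize <- function(table) {
  .stopIfNot(nrow(table) > 0L, "empty feature table")
  cols <- .featureColumns(table)
  lo <- vapply(table[cols], min, numeric(1))
  hi <- vapply(table[cols], max, numeric(1))
  ranges <- data.frame(feature = cols, min = lo, max = hi, row.names = NULL)
  list(table = applyNormalization(table, ranges), ranges = ranges)
}

#' @rdname minmaxNormalize
#' @param ranges fitted ranges from a previous [minmaxNormalize()] call.
#' @export
applyNormalization <- function(table, ranges) {
  for (i in seq_len(nrow(ranges))) {
    f <- ranges$feature[i]
    span <- ranges$max[i] - ranges$min[i]
    table[[f]] <- if (span > 0) (table[[f]] - ranges$min[i]) / span
    else rep(0, nrow(table))
  }
  table
}

#' Pearson correlation between feature columns
#'
#' Symmetric correlation matrix with unit diagonal; correlations involving a
#' constant column are defined as 0 with a warning.
#'
#' @param table feature data.frame with at least 3 rows.
#' @return correlation matrix over the feature columns.
#' @export
featureCorrelation <- function(table) {
  .stopIfNot(nrow(table) >= 3L, "at least 3 rows are required")
  X <- as.matrix(table[.featureColumns(table)])
  const <- apply(X, 2L, function(x) max(x) == min(x))
  if (any(const))
    warning("constant feature column(s): correlations set to 0",
            call. = FALSE)
  cm <- suppressWarnings(stats::cor(X))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  cm
}
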