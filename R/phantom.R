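#' @include AllClasses.R
NULL

#' Create a phantom specification
#'
#' Builds a validated [PhantomSpec-class]. The defaults emulate the image
#' properties the downstream stages are designed for: a 224x224 frame, a
#' breast half-ellipse flush with the left edge, dense-tissue texture whose
#' intensity stays clearly below the lesion, a lesion disk whose peak is the
#' breast maximum with a small quadratic shoulder, and all three artefacts
#' switched on.
#'
#' @param width,height image size in pixels.
#' @param breastCenter,breastSemiAxes breast half-ellipse geometry; defaults
#'   scale with the image size.
#' @param breastBaseIntensity,tissueTextureSigma tissue intensity model.
#' @param lesionCenter,lesionRadius,lesionIntensity,lesionEdgeDrop lesion disk
#'   geometry and radial intensity profile.
#' @param artefactFlags named logicals \code{border_frame}, \code{text_blob},
#'   \code{vertical_line}.
#' @param borderThickness drawn frame thickness in pixels.
#' @param densePatch,densePatchOffset dense-tissue patch toggle and its
#'   intensity offset below the lesion peak.
#' @param seed integer RNG seed.
#' @return a [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(seed = 7)
#' truth <- generatePhantom(spec)
#' @export
phantomSpec <- function(width = 224L, height = 224L,
                        breastCenter = c(height / 2, 7),
                        breastSemiAxes = c(0.42 * height, 0.36 * width),
                        breastBaseIntensity = 120, tissueTextureSigma = 12,
                        lesionCenter = c(round(height * 0.45), round(width * 0.22)),
                        lesionRadius = 12, lesionIntensity = 250,
                        lesionEdgeDrop = 3,
                        artefactFlags = c(border_frame = TRUE, text_blob = TRUE,
                                          vertical_line = TRUE),
                        borderThickness = 3L, densePatch = TRUE,
                        densePatchOffset = 14, seed = 1L) {
  new("PhantomSpec", width = as.integer(width), height = as.integer(height),
      breastCenter = as.numeric(breastCenter),
      breastSemiAxes = as.numeric(breastSemiAxes),
      breastBaseIntensity = breastBaseIntensity,
      tissueTextureSigma = tissueTextureSigma,
      lesionCenter = as.numeric(lesionCenter), lesionRadius = lesionRadius,
      lesionIntensity = lesionIntensity, lesionEdgeDrop = lesionEdgeDrop,
      artefactFlags = artefactFlags,
      borderThickness = as.integer(borderThickness),
      densePatch = densePatch, densePatchOffset = densePatchOffset,
      seed = as.integer(seed))
}

#' Generate a synthetic mammogram phantom
#'
#' Renders the phantom described by a [PhantomSpec-class] and returns the
#' image together with ground-truth breast, lesion and artefact masks. The
#' generator is deterministic: the same spec (including its seed) always
#' yields a bit-identical phantom. Excluding artefact pixels, the image
#' maximum is attained only inside the lesion mask; tissue (including the
#' dense patch) is clamped strictly below the lesion rim intensity.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomTruth-class] object.
#' @examples
#' truth <- generatePhantom(phantomSpec(seed = 3))
#' range(phantomImage(truth))
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  h <- spec@height; w <- spec@width
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)

  a <- spec@breastSemiAxes[1L]; b <- spec@breastSemiAxes[2L]
  # right half-ellipse: the flat side (chest wall) faces the left edge
  breast <- (((rr - spec@breastCenter[1L]) / a)^2 +
               ((cc - spec@breastCenter[2L]) / b)^2) <= 1 &
    cc >= spec@breastCenter[2L]

  # dense-tissue texture: smoothed white noise rescaled to the target sd
  noise <- matrix(rnorm(h * w), h, w)
  noise <- .gaussianBlur(noise, sigma = 2)
  noise <- noise / sd(noise) * spec@tissueTextureSigma

  img <- matrix(0, h, w)
  # tissue stays strictly below the lesion rim (peak - edge drop)
  tissueCap <- spec@lesionIntensity - spec@lesionEdgeDrop - 8
  img[breast] <- .clip255(pmin(spec@breastBaseIntensity + noise[breast],
                               tissueCap))

  # optional dense patch: slightly below the lesion peak, still under the cap+
  if (spec@densePatch) {
    pc <- c(spec@breastCenter[1L] + 0.3 * a, max(2, 0.45 * b))
    pr <- max(6, spec@lesionRadius * 0.8)
    patch <- ((rr - pc[1L])^2 + (cc - pc[2L])^2) <= pr^2 & breast
    img[patch] <- min(spec@lesionIntensity - spec@densePatchOffset, tissueCap)
  }

  # lesion disk with quadratic radial drop: exact maximum only at the centre
  d2 <- (rr - spec@lesionCenter[1L])^2 + (cc - spec@lesionCenter[2L])^2
  lesion <- d2 <= spec@lesionRadius^2
  img[lesion] <- spec@lesionIntensity -
    spec@lesionEdgeDrop * d2[lesion] / spec@lesionRadius^2

  artefact <- matrix(FALSE, h, w)
  flags <- spec@artefactFlags
  if (isTRUE(flags[["border_frame"]])) {
    bt <- spec@borderThickness
    frame <- rr <= bt | rr > h - bt | cc <= bt | cc > w - bt
    frame <- frame & !breast   # breast is flush left; keep its pixels intact
    img[frame] <- 255
    artefact <- artefact | frame
  }
  if (isTRUE(flags[["text_blob"]])) {
    nblob <- sample(2:4, 1L)
    for (i in seq_len(nblob)) {
      bh <- sample(6:14, 1L); bw <- sample(10:24, 1L)
      r0 <- sample(seq(10L, h - bh - 10L), 1L)
      c0 <- sample(seq(round(0.75 * w), w - bw - 6L), 1L)
      blob <- rr >= r0 & rr < r0 + bh & cc >= c0 & cc < c0 + bw & !breast
      img[blob] <- sample(230:255, 1L)
      artefact <- artefact | blob
    }
  }
  if (isTRUE(flags[["vertical_line"]])) {
    # near-vertical bright line touching the breast's right edge
    midRow <- round(spec@breastCenter[1L])
    edgeCol <- max(which(breast[midRow, ]))
    len <- round(0.55 * h)
    rowsLine <- seq(midRow - len %/% 2, midRow + len %/% 2)
    rowsLine <- rowsLine[rowsLine >= 1 & rowsLine <= h]
    slope <- runif(1L, -0.04, 0.04)
    colsLine <- round(edgeCol + slope * (rowsLine - midRow))
    keep <- colsLine >= 1 & colsLine <= w
    lineIdx <- cbind(rowsLine[keep], colsLine[keep])
    img[lineIdx] <- 255
    lineMask <- matrix(FALSE, h, w)
    lineMask[lineIdx] <- TRUE
    artefact <- artefact | lineMask
  }

  new("PhantomTruth", image = img, breastMask = breast, lesionMask = lesion,
      artefactMask = artefact, spec = spec)
}

#' Generate a labelled four-class phantom dataset
#'
#' Convenience wrapper producing one phantom per sample with class-dependent
#' lesion geometry (radius and rim drop vary by class, with per-sample
#' jitter), so that lesion shape and intensity descriptors carry class signal.
#' Class labels follow the benign/malignant calcification/mass convention
#' BC = 0, BM = 1, MC = 2, MM = 3.
#'
#' @param nPerClass phantoms per class.
#' @param seed integer seed controlling the whole dataset.
#' @param width,height phantom size.
#' @param artefacts logical; draw the three artefacts (default TRUE).
#' @return a list with \code{truths} (list of [PhantomTruth-class]),
#'   \code{labels} (integer codes 0..3) and \code{classes} (character names).
#' @export
generatePhantomDataset <- function(nPerClass = 30L, seed = 1L,
                                   width = 224L, height = 224L,
                                   artefacts = TRUE) {
  classes <- c("BC", "BM", "MC", "MM")
  radius <- c(BC = 7, BM = 14, MC = 10, MM = 18)
  edge <- c(BC = 2, BM = 3, MC = 4, MM = 5)
  set.seed(seed)
  specSeeds <- sample.int(2^30, 4L * nPerClass)
  truths <- vector("list", 4L * nPerClass)
  labels <- integer(4L * nPerClass)
  flags <- c(border_frame = artefacts, text_blob = artefacts,
             vertical_line = artefacts)
  i <- 0L
  for (k in seq_along(classes)) {
    for (j in seq_len(nPerClass)) {
      i <- i + 1L
      set.seed(specSeeds[i])
      rad <- max(4, radius[k] + runif(1L, -2, 2))
      ctr <- c(round(height * runif(1L, 0.38, 0.55)),
               round(width * runif(1L, 0.12, 0.24)))
      spec <- phantomSpec(width = width, height = height,
                          lesionCenter = ctr, lesionRadius = rad,
                          lesionEdgeDrop = edge[k],
                          artefactFlags = flags,
                          seed = specSeeds[i])
      truths[[i]] <- generatePhantom(spec)
      labels[i] <- k - 1L
    }
  }
  list(truths = truths, labels = labels, classes = classes)
}

#' Generate a synthetic labelled feature table
#'
#' Stands in for the extracted-feature dataset: \code{nClasses * nPerClass}
#' rows with exactly uniform class priors and integer labels
#' \code{0..nClasses-1}. Informative columns are class-conditional unit
#' Gaussians whose class means are offset by \code{classSeparation} standard
#' deviations in a cyclic one-feature-per-class pattern; noise columns are
#' class-independent standard normals. With \code{classSeparation = 0} the
#' table carries no class signal at all.
#'
#' @param nPerClass rows per class.
#' @param nClasses number of classes (default 4).
#' @param nFeatures total feature columns (default 16; when 16, the canonical
#'   lesion-descriptor names are used).
#' @param classSeparation between-class mean offset, in feature sd units.
#' @param noiseFeatures trailing columns carrying no class signal.
#' @param seed integer RNG seed.
#' @return a data.frame of features plus an integer \code{label} column, with
#'   attribute \code{informative} marking the informative column indices.
#' @examples
#' tab <- generateFeatureTable(nPerClass = 10, classSeparation = 6, seed = 1)
#' table(tab$label)
#' @export
generateFeatureTable <- function(nPerClass = 50L, nClasses = 4L,
                                 nFeatures = 16L, classSeparation = 4,
                                 noiseFeatures = 4L, seed = 1L) {
  .stopIfNot(nClasses >= 2L, "nClasses must be at least 2")
  .stopIfNot(nFeatures >= noiseFeatures,
             "noiseFeatures cannot exceed nFeatures")
  set.seed(seed)
  n <- nPerClass * nClasses
  labels <- rep(seq_len(nClasses) - 1L, each = nPerClass)
  nInf <- nFeatures - noiseFeatures
  X <- matrix(rnorm(n * nFeatures), n, nFeatures)
  for (j in seq_len(nInf)) {
    targetClass <- (j - 1L) %% nClasses           # class whose mean is offset
    X[labels == targetClass, j] <- X[labels == targetClass, j] + classSeparation
  }
  cols <- if (nFeatures == 16L) mammocadFeatureNames() else
    sprintf("feature%02d", seq_len(nFeatures))
  out <- as.data.frame(X)
  names(out) <- cols
  out$label <- labels
  attr(out, "informative") <- seq_len(nInf)
  out
}

#' Canonical names of the sixteen lesion descriptors
#'
#' @return character vector of length 16, in the documented column order.
#' @export
mammocadFeatureNames <- function() {
  c("area", "perimeter_area_ratio", "convex_area", "solidity", "circularity",
    "equivalent_diameter", "extent", "filled_area", "major_axis_length",
    "minor_axis_length", "mean_intensity", "std_intensity", "shannon_entropy",
    "glcm_entropy", "skewness", "kurtosis")
}
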