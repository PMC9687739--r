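#' @include AllClasses.R
NULL

.AUGMENT_NAMES <- c("hflip", "vflip", "hvflip", "rot_p30", "rot_p30_hflip",
                    "rot_m30", "rot_m30_hflip")

#' Construct the seven-transform augmentation set
#'
#' @param rotationFill intensity filled outside the rotated support
#'   (default 0, the mammogram background).
#' @param interpolation "bilinear" (default) or "nearest" for rotations;
#'   flips are exact pixel permutations either way.
#' @return an [AugmentSet-class] object.
#' @export
augmentSet <- function(rotationFill = 0, interpolation = "bilinear") {
  new("AugmentSet", transforms = .AUGMENT_NAMES, rotationFill = rotationFill,
      interpolation = interpolation)
}

#' Flip an image horizontally or vertically
#'
#' \code{flipHorizontal} maps pixel (r, c) to (r, n - 1 - c) (mirror across
#' the vertical axis); \code{flipVertical} mirrors across the horizontal
#' axis. Both are involutions and exact permutations of the pixels.
#'
#' @param img numeric matrix.
#' @return the flipped image.
#' @export
flipHorizontal <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' @rdname flipHorizontal
#' @export
flipVertical <- function(img) img[rev(seq_len(nrow(img))), , drop = FALSE]

#' Rotate an image about its centre
#'
#' Rotation on the original canvas (no expansion) by inverse mapping;
#' positive angles rotate counter-clockwise in the usual image convention.
#' Pixels sampled outside the input are set to \code{fill}. Multiples of 90
#' degrees are exact pixel permutations (cospi/sinpi are used, so 180-degree
#' rotation reproduces the combined horizontal+vertical flip bit-exactly).
#'
#' @param img numeric matrix.
#' @param angle rotation angle in degrees.
#' @param fill intensity for out-of-support pixels.
#' @param interpolation "bilinear" or "nearest".
#' @return the rotated image, same shape as the input.
#' @export
rotateImage <- function(img, angle, fill = 0,
                        interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; ccen <- (nc + 1) / 2
  co <- cospi(angle / 180); si <- sinpi(angle / 180)
  r <- matrix(seq_len(nr), nr, nc) - cr
  c2 <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - ccen
  # inverse rotation of the output grid back into the source image
  sr <- co * r + si * c2 + cr
  sc <- -si * r + co * c2 + ccen
  out <- matrix(fill, nr, nc)
  if (interpolation == "nearest") {
    ir <- round(sr); ic <- round(sc)
    ok <- ir >= 1 & ir <= nr & ic >= 1 & ic <= nc
    out[ok] <- img[cbind(ir[ok], ic[ok])]
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ok <- r0 >= 1 & r0 + (fr > 0) <= nr & c0 >= 1 & c0 + (fc > 0) <= nc
  g <- function(dr, dc) {
    ri <- pmin(pmax(r0 + dr, 1L), nr); ci <- pmin(pmax(c0 + dc, 1L), nc)
    img[cbind(as.vector(ri), as.vector(ci))]
  }
  v <- (1 - fr) * (1 - fc) * g(0L, 0L) + (1 - fr) * fc * g(0L, 1L) +
    fr * (1 - fc) * g(1L, 0L) + fr * fc * g(1L, 1L)
  out[ok] <- matrix(v, nr, nc)[ok]
  out
}

#' Apply the seven geometric augmentations to one image
#'
#' Returns the seven augmented variants, in the set's fixed order: horizontal
#' flip, vertical flip, combined flip, +30-degree rotation, +30-degree
#' rotation with horizontal flip, -30-degree rotation, -30-degree rotation
#' with horizontal flip. All outputs share the input's shape; the combined
#' flip equals a 180-degree rotation bit-exactly.
#'
#' @param img numeric matrix in [0, 255].
#' @param set an [AugmentSet-class] (default [augmentSet()]).
#' @return a named list of 7 images.
#' @examples
#' length(augmentImage(matrix(runif(36, 0, 255), 6, 6)))
#' @export
augmentImage <- function(img, set = augmentSet()) {
  .assertImage(img)
  validObject(set)
  fill <- set@rotationFill
  interp <- set@interpolation
  rp30 <- rotateImage(img, 30, fill, interp)
  rm30 <- rotateImage(img, -30, fill, interp)
  out <- list(
    hflip = flipHorizontal(img),
    vflip = flipVertical(img),
    hvflip = flipHorizontal(flipVertical(img)),
    rot_p30 = rp30,
    rot_p30_hflip = flipHorizontal(rp30),
    rot_m30 = rm30,
    rot_m30_hflip = flipHorizontal(rm30))
  out[set@transforms]
}

#' Augment a labelled image set eightfold
#'
#' Keeps every original image and appends its seven augmented variants, so
#' the output is exactly eight times the input, each variant carrying its
#' source's label. Provenance (source index and transform name) is returned
#' as a manifest.
#'
#' @param images list of numeric matrices.
#' @param labels vector of labels aligned with \code{images}.
#' @param set an [AugmentSet-class].
#' @return list with \code{images}, \code{labels} and a \code{manifest}
#'   data.frame (source, transform, label).
#' @export
augmentDataset <- function(images, labels, set = augmentSet()) {
  .stopIfNot(length(images) == length(labels),
             "images and labels must be aligned")
  n <- length(images)
  outImages <- vector("list", 8L * n)
  k <- 0L
  for (i in seq_len(n)) {
    aug <- augmentImage(images[[i]], set)
    block <- c(list(original = images[[i]]), aug)
    for (j in seq_along(block)) {
      k <- k + 1L
      outImages[[k]] <- block[[j]]
    }
  }
  outLabels <- rep(labels, each = 8L)
  manifest <- data.frame(
    source = rep(seq_len(n), each = 8L),
    transform = rep(c("original", .AUGMENT_NAMES), times = n),
    label = outLabels)
  list(images = outImages, labels = outLabels, manifest = manifest)
}
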