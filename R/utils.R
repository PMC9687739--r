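# Internal helpers shared across modules: image validation, padding,
# shift-and-accumulate 2-D convolution, hole filling.

.assertImage <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (anyNA(img))
    stop(sprintf("'%s' contains missing values", arg), call. = FALSE)
  if (min(img) < 0 || max(img) > 255)
    stop(sprintf("'%s' intensities must lie in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

.assertMask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("'%s' must be a logical matrix", arg), call. = FALSE)
  invisible(mask)
}

.sameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must share the same dimensions", call. = FALSE)
  invisible(TRUE)
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)
.clip255 <- function(x) pmin(pmax(x, 0), 255)

# Pad a matrix by `m` pixels on every side; mode "value" or "replicate".
.padMatrix <- function(img, m, mode = c("value", "replicate"), value = 0) {
  mode <- match.arg(mode)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(value, nr + 2L * m, nc + 2L * m)
  out[(m + 1L):(m + nr), (m + 1L):(m + nc)] <- img
  if (mode == "replicate" && m > 0L) {
    ri <- c(rep(1L, m), seq_len(nr), rep(nr, m))
    ci <- c(rep(1L, m), seq_len(nc), rep(nc, m))
    out <- img[ri, ci, drop = FALSE]
  }
  out
}

# 2-D convolution (correlation, kernel not flipped; all kernels used here are
# symmetric) returning a matrix of the input's size. Shift-and-accumulate:
# cheap for the small kernels used (Sobel 3x3, Gaussian <= 13x13).
.conv2 <- function(img, kern, pad = c("value", "replicate"), value = 0) {
  pad <- match.arg(pad)
  kr <- nrow(kern); kc <- ncol(kern)
  mr <- (kr - 1L) %/% 2L; mc <- (kc - 1L) %/% 2L
  m <- max(mr, mc)
  big <- .padMatrix(img, m, mode = pad, value = value)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      k <- kern[i, j]
      if (k == 0) next
      rows <- (m - mr + i - 1L) + seq_len(nr)
      cols <- (m - mc + j - 1L) + seq_len(nc)
      out <- out + k * big[rows, cols]
    }
  }
  out
}

.gaussianKernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate padding.
.gaussianBlur <- function(img, sigma, radius = ceiling(3 * sigma)) {
  k <- .gaussianKernel1d(sigma, radius)
  img <- .conv2(img, matrix(k, ncol = 1L), pad = "replicate")
  .conv2(img, matrix(k, nrow = 1L), pad = "replicate")
}

# Fill interior holes of a mask: background components (4-connected, the
# complement connectivity of the 8-connected foreground) that do not touch
# the image border are holes.
.fillHoles <- function(mask) {
  lab <- .cc_label(!mask, 4L)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border != 0L]
  mask | (lab != 0L & !(lab %in% border))
}

.stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
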