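# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results through different algorithms than the
# package (queue-based BFS, double loops, direct formulas).

# Brute-force flood fill: plain queue BFS over pixels >= threshold.
bfsFloodOracle <- function(img, seed, threshold, connectivity = 8L) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- if (connectivity == 8L)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  out <- matrix(FALSE, nr, nc)
  if (img[seed[1], seed[2]] < threshold) stop("seed below threshold")
  queue <- list(seed)
  out[seed[1], seed[2]] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(offs))) {
      r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          !out[r, c] && img[r, c] >= threshold) {
        out[r, c] <- TRUE
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  out
}

# Label connected components by repeated BFS (independent of the compiled
# labelling); returns a list of logical masks sorted by decreasing area.
bfsComponentsOracle <- function(mask, connectivity = 8L) {
  comps <- list()
  remaining <- mask
  while (any(remaining)) {
    seedIdx <- which(remaining, arr.ind = TRUE)[1, ]
    field <- matrix(0, nrow(mask), ncol(mask))
    field[remaining] <- 1
    comp <- bfsFloodOracle(field, seedIdx, 1, connectivity)
    comps[[length(comps) + 1]] <- comp
    remaining <- remaining & !comp
  }
  comps[order(vapply(comps, sum, numeric(1)), decreasing = TRUE)]
}

# Direct windowed SSIM: explicit loop over all valid window positions with
# Gaussian weights built in place.
ssimOracle <- function(ref, test, window = 11L, sigma = 1.5, maxLevel = 255) {
  m <- (window - 1L) %/% 2L
  x <- seq(-m, m)
  k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  W <- outer(k1, k1)
  c1 <- (0.01 * maxLevel)^2; c2 <- (0.03 * maxLevel)^2
  vals <- c()
  for (i in (m + 1):(nrow(ref) - m)) {
    for (j in (m + 1):(ncol(ref) - m)) {
      a <- ref[(i - m):(i + m), (j - m):(j + m)]
      b <- test[(i - m):(i + m), (j - m):(j + m)]
      mx <- sum(W * a); my <- sum(W * b)
      vx <- sum(W * a^2) - mx^2; vy <- sum(W * b^2) - my^2
      vxy <- sum(W * a * b) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * vxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# Rasterised disk mask and flat-intensity image.
diskFixture <- function(radius, size = 2L * radius + 37L, intensity = 200) {
  ctr <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  mask <- (rr - ctr)^2 + (cc - ctr)^2 <= radius^2
  img <- matrix(0, size, size)
  img[mask] <- intensity
  list(mask = mask, img = img)
}

# The published per-model test accuracies (percent) used by the ensemble
# selection rule's worked example.
publishedTestAccuracies <- function() {
  c(KNN = 92.82, SVC = 92.82, DT = 94.62, RF = 95.91, MLP = 70.61,
    AB = 54.39, XGB = 95.40, GNB = 43.97, SVM = 36.96, SGD = 40.54,
    LR = 42.90)
}

artefactFreeSpec <- function(seed = 1L, ...) {
  phantomSpec(seed = seed,
              artefactFlags = c(border_frame = FALSE, text_blob = FALSE,
                                vertical_line = FALSE), ...)
}
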