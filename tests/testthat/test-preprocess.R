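test_that("border mask zeroes the frame, keeps the interior, is idempotent", {
  img <- matrix(50, 30, 40)
  img[1:3, ] <- 255; img[28:30, ] <- 255; img[, 1:3] <- 255; img[, 38:40] <- 255
  out <- applyBorderMask(img, 5)
  expected <- matrix(50, 30, 40)
  expected[c(1:5, 26:30), ] <- 0
  expected[, c(1:5, 36:40)] <- 0
  expect_identical(out, expected)
  expect_identical(applyBorderMask(out, 5), out)
  expect_identical(applyBorderMask(matrix(0, 10, 10), 2), matrix(0, 10, 10))
  expect_error(applyBorderMask(img, 20), "half the smaller")
})

test_that("otsu binarisation separates a two-level image exactly", {
  strip <- function(x) { attr(x, "threshold") <- NULL; x }
  img <- matrix(10, 8, 8); img[3:6, 3:6] <- 200
  m <- binarize(img, "otsu")
  expect_identical(strip(m), img >= 200)
  # exhaustive-search oracle: any threshold in (10, 200] maximises the
  # between-class variance; the mask must equal the 200-level set
  expect_true(attr(m, "threshold") > 10 && attr(m, "threshold") <= 200)
  expect_identical(strip(binarize(matrix(0, 4, 4), "fixed",
                                  fixedThreshold = 1)),
                   matrix(FALSE, 4, 4))
  expect_identical(strip(binarize(matrix(7, 4, 4), "fixed",
                                  fixedThreshold = 0)),
                   matrix(TRUE, 4, 4))
  expect_message(binarize(matrix(9, 4, 4), "otsu"), "constant")
})

test_that("largest component keeps the biggest blob, fills holes, breaks ties", {
  m <- matrix(FALSE, 12, 12)
  m[2:7, 2:7] <- TRUE        # 36 px blob with a hole
  m[4:5, 4:5] <- FALSE
  m[10:11, 10:11] <- TRUE    # 4 px blob
  out <- largestComponentMask(m)
  comps <- bfsComponentsOracle(m)
  expect_identical(sum(out), 36L)                 # hole filled
  expect_true(all(out[comps[[1]]]))
  expect_false(any(out & comps[[2]]))
  # single blob is unchanged
  single <- matrix(FALSE, 6, 6); single[2:4, 2:4] <- TRUE
  expect_identical(largestComponentMask(single), single)
  # tie: keep the component whose first pixel comes first in row-major order
  tie <- matrix(FALSE, 8, 8)
  tie[5, 2:3] <- TRUE        # area 2, top-left-most pixel (5, 2)
  tie[2, 6:7] <- TRUE        # area 2, top-left-most pixel (2, 6)
  out2 <- largestComponentMask(tie)
  expect_identical(which(out2, arr.ind = TRUE)[1, ],
                   c(row = 2L, col = 6L))
  expect_error(largestComponentMask(matrix(FALSE, 3, 3)), "no foreground")
})

test_that("vertical line removal erases lines and ignores other structure", {
  # 1-px vertical bright line, length 100
  img <- matrix(0, 120, 60)
  img[11:110, 30] <- 255
  out <- removeVerticalLines(img)
  expect_true(all(out[11:110, 30] == 0))
  # pixels far from the line are untouched
  far <- abs(col(img) - 30) > 4
  expect_identical(out[far], img[far])
  expect_gt(nrow(attr(out, "lines")), 0)

  # a horizontal line is outside the angular tolerance and survives
  imgH <- matrix(0, 60, 120)
  imgH[30, 11:110] <- 255
  outH <- removeVerticalLines(imgH, angleTol = 10)
  expect_identical(unclass(outH)[, ], imgH)
  expect_equal(nrow(attr(outH, "lines")), 0)

  # no straight bright lines at all -> unchanged
  blob <- matrix(0, 60, 60); blob[25:35, 25:35] <- 180
  outB <- removeVerticalLines(blob)
  expect_identical(unclass(outB)[, ], blob)
})

test_that("gamma correction follows the power law and its monotonicity", {
  img <- matrix(c(0, 127.5, 255), 1, 3)
  out <- gammaCorrect(img, gamma = 2, gain = 1)
  expect_equal(out[1, 2], 0.25 * 255)     # 0.5^2 on the normalised scale
  expect_equal(out[1, 1], 0)
  expect_equal(out[1, 3], 255)            # V_in = 1 -> gain for any gamma
  expect_identical(gammaCorrect(img, gamma = 1, gain = 1), img)
  # gamma < 1 brightens pixelwise, gamma > 1 darkens (normalised scale)
  rimg <- matrix(runif(100, 0, 255), 10, 10)
  expect_true(all(gammaCorrect(rimg, 0.5) >= rimg - 1e-9))
  expect_true(all(gammaCorrect(rimg, 2) <= rimg + 1e-9))
})

test_that("clahe equalises contrast and preserves constants and range", {
  expect_identical(unique(as.vector(clahe(matrix(80, 32, 32)))) |> length(),
                   1L)
  # low-contrast ramp gains contrast
  ramp <- matrix(rep(seq(100, 130, length.out = 64), each = 64), 64, 64)
  out <- clahe(ramp, clipLimit = 1, tileGrid = c(8, 8))
  expect_gt(sd(out), sd(ramp))
  expect_true(all(out >= 0 & out <= 255))
  # single-tile CLAHE equals global clipped-histogram equalisation: direct
  # histogram/CDF oracle
  set.seed(4)
  img <- matrix(sample(90:160, 24 * 24, replace = TRUE), 24, 24)
  out1 <- clahe(img, clipLimit = 2, tileGrid = c(1, 1))
  h <- tabulate(floor(img) + 1L, nbins = 256L)
  clip <- 2 * length(img) / 256
  excess <- sum(pmax(h - clip, 0))
  h <- pmin(h, clip) + excess / 256
  lut <- round(cumsum(h) / length(img) * 255)
  expect_equal(out1, matrix(lut[floor(img) + 1L], 24, 24))
  expect_error(clahe(matrix(1, 4, 4), tileGrid = c(8, 8)), "exceed")
})

test_that("the full preprocessing chain cleans phantoms and isolates the breast", {
  truth <- generatePhantom(phantomSpec(seed = 21))
  pre <- preprocessImage(phantomImage(truth))
  outsideArt <- artefactMask(truth) & !breastMask(truth)
  expect_true(all(pre[outsideArt] == 0))

  truthClean <- generatePhantom(artefactFreeSpec(seed = 22))
  preClean <- preprocessImage(phantomImage(truthClean))
  bm <- attr(preClean, "breastMask")
  iou <- sum(bm & breastMask(truthClean)) / sum(bm | breastMask(truthClean))
  expect_gte(iou, 0.95)
  expect_true(all(preClean >= 0 & preClean <= 255))
  expect_identical(dim(preClean), dim(phantomImage(truthClean)))

  expect_error(preprocessImage(matrix(0, 64, 64)), "no foreground")
})
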