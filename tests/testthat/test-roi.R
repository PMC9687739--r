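test_that("dynamic threshold reproduces hand-computed toy decisions", {
  # 5x5 grid: one pixel at 200, five at 190, rest 100
  img <- matrix(100, 5, 5)
  img[3, 3] <- 200
  img[1, 1:5] <- 190
  d <- computeDynamicThreshold(img, delta = 10, minRegion = 3)
  expect_equal(d@maxIntensity, 200)
  expect_equal(d@nearMaxIntensity, 190)
  expect_equal(d@countMax, 1L)
  expect_equal(d@countNearMax, 5L)
  expect_equal(d@chosenThreshold, 190)          # 1 < 3 -> relax
  expect_identical(d@ruleFired, "NEAR_MAX_EXPANDED")

  d1 <- computeDynamicThreshold(img, delta = 10, minRegion = 1)
  expect_equal(d1@chosenThreshold, 200)
  expect_identical(d1@ruleFired, "MAX_SUFFICIENT")

  # constant image: a single level, all pixels at the maximum
  dc <- computeDynamicThreshold(matrix(180, 4, 4))
  expect_equal(dc@chosenThreshold, 180)
  expect_equal(dc@countMax, 16L)
  expect_identical(dc@ruleFired, "MAX_SUFFICIENT")

  expect_error(computeDynamicThreshold(matrix(0, 4, 4)), "all-zero")
})

test_that("seed placement uses the brightest centroid with nearest-pixel snap", {
  img <- matrix(0, 10, 10)
  img[8, 4] <- 255
  d <- computeDynamicThreshold(img, minRegion = 1)
  expect_identical(findSeed(img, d), c(8L, 4L))

  # two brightest pixels on a bright row: centroid lands between them
  img2 <- matrix(0, 5, 5)
  img2[1, 1:3] <- 255
  img2[1, 2] <- 255
  d2 <- computeDynamicThreshold(img2, minRegion = 1)
  expect_identical(findSeed(img2, d2), c(1L, 2L))

  # dark gap under the centroid: snap to the nearest (row-major tie-break)
  img3 <- matrix(0, 3, 5)
  img3[1, 1] <- 255; img3[1, 5] <- 255
  d3 <- computeDynamicThreshold(img3, delta = 10, minRegion = 3)
  # centroid (1, 3) has intensity 0 < threshold 245 -> nearest of the two
  expect_identical(findSeed(img3, d3), c(1L, 1L))
})

test_that("region growing equals a brute-force flood fill on random images", {
  set.seed(42)
  for (trial in 1:100) {
    img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    seed <- c(sample(16, 1), sample(16, 1))
    thr <- img[seed[1], seed[2]] - sample(0:40, 1)
    conn <- sample(c(4L, 8L), 1)
    expect_identical(regionGrow(img, seed, thr, conn),
                     bfsFloodOracle(img, seed, thr, conn))
  }
})

test_that("region growing honours connectivity and stays connected", {
  img <- matrix(0, 5, 5)
  img[2:4, 3] <- 255; img[3, 2:4] <- 255   # plus shape
  img[1, 1] <- 255                         # disconnected corner
  m4 <- regionGrow(img, c(3, 3), 255, 4)
  expect_equal(sum(m4), 5L)
  expect_false(m4[1, 1])
  expect_identical(regionGrow(matrix(200, 1, 1), c(1, 1), 200),
                   matrix(TRUE, 1, 1))
  expect_error(regionGrow(img, c(1, 2), 255), "below threshold")
  # monotone: lowering the threshold never shrinks the region
  set.seed(8)
  rimg <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  sd2 <- which(rimg == max(rimg), arr.ind = TRUE)[1, ]
  hi <- regionGrow(rimg, sd2, max(rimg) - 20)
  lo <- regionGrow(rimg, sd2, max(rimg) - 60)
  expect_true(all(lo[hi]))
})

test_that("ROI extraction satisfies its contract on structured inputs", {
  truth <- generatePhantom(artefactFreeSpec(seed = 13))
  roi <- extractROI(phantomImage(truth))
  m <- roiMask(roi)
  expect_true(m[roiSeed(roi)[1], roiSeed(roi)[2]])
  expect_true(all(roiImage(roi)[m] >= chosenThreshold(roi)))
  expect_true(all(roiImage(roi)[!m] == 0))
  expect_true(all(roiImage(roi) <= phantomImage(truth)))
  # one connected component
  comps <- bfsComponentsOracle(m)
  expect_length(comps, 1L)

  # dense near-max patch disconnected from the lesion is never absorbed
  img <- matrix(100, 40, 40)
  img[10:14, 10:14] <- 250                # lesion block (max)
  img[30:33, 30:33] <- 243                # near-max patch, disconnected
  roi2 <- extractROI(img, delta = 10, minRegion = 30)
  expect_identical(ruleFired(roi2), "NEAR_MAX_EXPANDED")
  expect_equal(chosenThreshold(roi2), 240)
  expect_false(any(roiMask(roi2)[30:33, 30:33]))
  expect_true(all(roiMask(roi2)[10:14, 10:14]))

  # constant image: whole support becomes the ROI
  const <- matrix(120, 9, 9)
  roi3 <- extractROI(const)
  expect_true(all(roiMask(roi3)))
  expect_identical(roiImage(roi3), const)
})
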