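test_that("disk descriptors match analytic values", {
  d <- diskFixture(32)
  f <- computeFeatures(d$mask, d$img)
  expect_lt(abs(f[["area"]] - pi * 32^2) / (pi * 32^2), 0.02)
  expect_lt(abs(f[["equivalent_diameter"]] - 64) / 64, 0.02)
  expect_gte(f[["circularity"]], 0.92)
  expect_lte(f[["circularity"]], 1.05)
  expect_gte(f[["solidity"]], 0.98)
  expect_equal(f[["shannon_entropy"]], 0)      # constant intensity
  expect_equal(f[["glcm_entropy"]], 0)
  expect_equal(f[["mean_intensity"]], 200)
  expect_equal(f[["std_intensity"]], 0)
  expect_lt(abs(f[["major_axis_length"]] - 64) / 64, 0.05)
  expect_lt(abs(f[["minor_axis_length"]] - 64) / 64, 0.05)
})

test_that("squares, two-tone regions and holes behave as designed", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  fs <- computeFeatures(sq, matrix(100, 20, 20))
  expect_equal(fs[["extent"]], 1)
  expect_equal(fs[["area"]], 100)
  expect_equal(fs[["filled_area"]], 100)

  # two-tone: entropy exactly 1 bit, skewness 0
  img2 <- matrix(100, 20, 20); img2[6:15, 6:10] <- 60
  f2 <- computeFeatures(sq, img2)
  expect_equal(f2[["shannon_entropy"]], 1)
  expect_equal(f2[["skewness"]], 0, tolerance = 1e-12)
  expect_equal(f2[["kurtosis"]], 1, tolerance = 1e-12)  # two-point dist

  # interior hole: filled area equals the hole-free region
  hole <- sq; hole[9:11, 9:11] <- FALSE
  fh <- computeFeatures(hole, matrix(100, 20, 20))
  expect_equal(fh[["area"]], 91)
  expect_equal(fh[["filled_area"]], 100)
  expect_gt(fh[["filled_area"]], fh[["area"]])

  expect_error(computeFeatures(matrix(FALSE, 4, 4), matrix(0, 4, 4)),
               "empty mask")
})

test_that("scaling and rotation invariances hold within discretisation", {
  d1 <- diskFixture(16); d2 <- diskFixture(32)
  f1 <- computeFeatures(d1$mask, d1$img)
  f2 <- computeFeatures(d2$mask, d2$img)
  expect_equal(f2[["area"]] / f1[["area"]], 4, tolerance = 0.05)
  expect_equal(f2[["equivalent_diameter"]] / f1[["equivalent_diameter"]], 2,
               tolerance = 0.02)
  for (nm in c("circularity", "solidity", "extent"))
    expect_equal(f2[[nm]] / f1[[nm]], 1, tolerance = 0.05)

  # 90-degree rotation: all 16 descriptors preserved (axes swap-invariant)
  set.seed(6)
  blob <- matrix(FALSE, 30, 30); blob[8:20, 10:25] <- TRUE
  img <- matrix(0, 30, 30); img[blob] <- sample(50:200, sum(blob), TRUE)
  fA <- computeFeatures(blob, img)
  rot <- function(m) t(m)[, nrow(m):1]
  fB <- computeFeatures(rot(blob), rot(img))
  for (nm in names(fA)) expect_equal(fB[[nm]], fA[[nm]], tolerance = 0.02)

  # background perturbation changes nothing
  imgBg <- img; imgBg[!blob] <- 255
  expect_identical(computeFeatures(blob, imgBg), fA)
})

test_that("feature tables assemble, encode labels and skip failures", {
  truths <- lapply(1:4, function(s)
    generatePhantom(artefactFreeSpec(seed = s)))
  rois <- lapply(truths, function(t) extractROI(phantomImage(t)))
  tab <- buildFeatureTable(rois, c("BC", "BM", "MC", "MM"))
  expect_equal(nrow(tab), 4L)
  expect_identical(tab$label, 0:3)
  expect_identical(setdiff(names(tab), c("image_id", "label")),
                   mammocadFeatureNames())
  expect_false(anyNA(tab))
  expect_equal(nrow(buildFeatureTable(list(), integer(0))), 0L)
  expect_error(encodeClassLabels(c("BC", "XX")), "among")
})

test_that("min-max normalisation fits, applies and extrapolates as stated", {
  tab <- data.frame(a = c(2, 4, 6), b = c(5, 5, 5), label = 0:2)
  norm <- minmaxNormalize(tab)
  expect_equal(norm$table$a, c(0, 0.5, 1))
  expect_equal(norm$table$b, c(0, 0, 0))       # constant column
  expect_identical(norm$table$label, 0:2)
  held <- applyNormalization(data.frame(a = 8, b = 9, label = 0), norm$ranges)
  expect_equal(held$a, 1.5)                    # outside [0, 1], not clipped
})

test_that("feature correlations are symmetric with unit diagonal", {
  set.seed(11)
  tab <- data.frame(x = rnorm(1000), label = 0)
  tab$y <- tab$x
  tab$z <- rnorm(1000)
  cm <- featureCorrelation(tab)
  expect_identical(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(cm["x", "y"], 1)
  expect_lt(abs(cm["x", "z"]), 0.1)            # independent columns
  expect_warning(featureCorrelation(data.frame(a = rnorm(5), b = rep(1, 5),
                                               label = 0)),
                 "constant")
})
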