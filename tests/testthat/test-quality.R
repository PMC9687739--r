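test_that("mse/rmse match direct summation and closed forms", {
  expect_equal(imageMSE(matrix(0, 2, 2), matrix(2, 2, 2)), 4)
  expect_equal(imageMSE(matrix(5, 3, 3), matrix(5, 3, 3)), 0)
  expect_equal(imageRMSE(matrix(0, 2, 2), matrix(3, 2, 2)), 3)
  set.seed(7)
  a <- matrix(runif(64, 0, 255), 8, 8)
  b <- matrix(runif(64, 0, 255), 8, 8)
  # double-loop oracle
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(imageMSE(a, b), acc / 64)
  expect_equal(imageRMSE(a, b), sqrt(acc / 64))
  expect_equal(imageMSE(a, b), imageMSE(b, a))
  expect_error(imageMSE(a, matrix(0, 4, 4)), "dimensions")
})

test_that("psnr follows 20 log10(MAX/rmse) with an Inf sentinel", {
  a <- matrix(0, 4, 4)
  b <- matrix(255, 4, 4)        # mse = MAX^2 -> 0 dB
  expect_equal(imagePSNR(a, b), 0)
  expect_identical(imagePSNR(a, a), Inf)
  c2 <- matrix(4.0472, 4, 4)    # mse ~ 16.38 as in the published examples
  expect_equal(imagePSNR(a, c2), 20 * log10(255 / 4.0472), tolerance = 1e-6)
  # strictly decreasing in mse at fixed MAX
  expect_gt(imagePSNR(a, matrix(1, 4, 4)), imagePSNR(a, matrix(2, 4, 4)))
})

test_that("ssim matches its closed forms and a direct windowed oracle", {
  set.seed(3)
  a <- matrix(runif(22 * 22, 0, 255), 22, 22)
  expect_equal(imageSSIM(a, a), 1)
  # constant images: variance terms vanish, luminance term remains
  c1 <- (0.01 * 255)^2
  av <- 240; bv <- 15
  expect_equal(imageSSIM(matrix(av, 15, 15), matrix(bv, 15, 15)),
               (2 * av * bv + c1) / (av^2 + bv^2 + c1), tolerance = 1e-9)
  expect_lt(imageSSIM(matrix(240, 15, 15), matrix(15, 15, 15)), 0.2)
  # independent per-window computation
  b <- matrix(runif(22 * 22, 0, 255), 22, 22)
  expect_equal(imageSSIM(a, b), ssimOracle(a, b), tolerance = 1e-8)
  expect_equal(imageSSIM(a, b), imageSSIM(b, a), tolerance = 1e-12)
})

test_that("quality report bundles consistent metrics and gates sensibly", {
  set.seed(9)
  ref <- matrix(runif(24 * 24, 60, 200), 24, 24)
  test <- pmin(pmax(ref + rnorm(24 * 24, 0, 4), 0), 255)
  rep <- qualityReport(ref, test)
  expect_equal(rep@rmse, sqrt(rep@mse))
  expect_lte(rep@ssim, 1)
  expect_false(qualityGate(qualityReport(ref, ref), mseMax = 0.5))
  expect_true(qualityGate(rep, mseMax = 0.5))      # mse >> 0.5 flags
})
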