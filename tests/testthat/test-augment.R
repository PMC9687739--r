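test_that("flips are the stated permutations and involutions", {
  set.seed(1)
  img <- matrix(sample(0:255, 48, replace = TRUE), 6, 8)
  h <- flipHorizontal(img)
  for (r in 1:6) for (c in 1:8) expect_identical(h[r, c], img[r, 8 + 1 - c])
  expect_identical(flipHorizontal(h), img)
  expect_identical(flipVertical(flipVertical(img)), img)
  # flips preserve the intensity histogram exactly
  expect_identical(sort(as.vector(h)), sort(as.vector(img)))
})

test_that("the combined flip equals a 180-degree rotation bit-exactly", {
  set.seed(2)
  img <- matrix(runif(7 * 9, 0, 255), 7, 9)
  hv <- flipHorizontal(flipVertical(img))
  expect_identical(hv, flipVertical(flipHorizontal(img)))
  expect_identical(hv, rotateImage(img, 180))
})

test_that("augmentImage yields seven same-shaped variants in fixed order", {
  set.seed(3)
  img <- matrix(runif(20 * 20, 0, 255), 20, 20)
  out <- augmentImage(img)
  expect_length(out, 7L)
  expect_identical(names(out), c("hflip", "vflip", "hvflip", "rot_p30",
                                 "rot_p30_hflip", "rot_m30", "rot_m30_hflip"))
  for (o in out) expect_identical(dim(o), dim(img))
  expect_identical(out$rot_p30_hflip, flipHorizontal(out$rot_p30))
})

test_that("rotation round trip is near-lossless away from borders", {
  set.seed(4)
  img <- matrix(0, 64, 64)
  img[20:44, 20:44] <- .gaussianNoiseFree <- 120 +
    matrix(round(30 * sin(seq(0, 6, length.out = 25))), 25, 25, byrow = TRUE)
  back <- rotateImage(rotateImage(img, 30), -30)
  interior <- 24:40
  expect_lte(mean(abs(back[interior, interior] - img[interior, interior])), 2)
})

test_that("dataset augmentation grows exactly eightfold with label provenance", {
  set.seed(5)
  imgs <- replicate(10, matrix(runif(64, 0, 255), 8, 8), simplify = FALSE)
  labs <- rep(0:4, each = 2)
  out <- augmentDataset(imgs, labs)
  expect_length(out$images, 80L)
  expect_length(out$labels, 80L)
  expect_equal(as.vector(table(out$labels)), rep(16L, 5))
  expect_equal(nrow(out$manifest), 80L)
  expect_identical(out$manifest$transform[1:8],
                   c("original", "hflip", "vflip", "hvflip", "rot_p30",
                     "rot_p30_hflip", "rot_m30", "rot_m30_hflip"))
  expect_identical(out$images[[1]], imgs[[1]])
  # empty input
  empty <- augmentDataset(list(), integer(0))
  expect_length(empty$images, 0L)
  expect_equal(nrow(empty$manifest), 0L)
  expect_error(augmentDataset(imgs, labs[-1]), "aligned")
})
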