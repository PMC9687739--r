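test_that("phantom generation is deterministic and respects its geometry", {
  spec <- phantomSpec(seed = 11)
  t1 <- generatePhantom(spec)
  t2 <- generatePhantom(spec)
  expect_identical(phantomImage(t1), phantomImage(t2))
  expect_identical(lesionMask(t1), lesionMask(t2))

  expect_identical(dim(phantomImage(t1)), c(224L, 224L))
  expect_true(all(phantomImage(t1) >= 0 & phantomImage(t1) <= 255))
  # lesion inside breast; artefacts intersect breast only along the line
  expect_true(all(breastMask(t1)[lesionMask(t1)]))
})

test_that("the lesion is the intensity maximum of the artefact-free breast", {
  spec <- phantomSpec(seed = 5, lesionIntensity = 250,
                      breastBaseIntensity = 120)
  truth <- generatePhantom(spec)
  img <- phantomImage(truth)
  nonArt <- !artefactMask(truth)
  expect_equal(max(img[nonArt]), 250)
  atMax <- img == 250 & nonArt
  expect_true(any(atMax))
  expect_true(all(lesionMask(truth)[atMax]))
  # tissue (breast minus lesion) stays strictly below the lesion rim
  tissue <- breastMask(truth) & !lesionMask(truth) & nonArt
  expect_lt(max(img[tissue]), min(img[lesionMask(truth)]))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantomSpec(lesionCenter = c(112, 200), lesionRadius = 12),
               "inside the breast")
  expect_error(phantomSpec(lesionIntensity = 130, breastBaseIntensity = 120,
                           tissueTextureSigma = 12),
               "3 \\* tissueTextureSigma")
})

test_that("feature tables have uniform priors and the stated class structure", {
  tab <- generateFeatureTable(nPerClass = 50, nClasses = 4, seed = 2)
  expect_equal(nrow(tab), 200L)
  expect_equal(sum(names(tab) != "label"), 16L)
  expect_equal(as.vector(table(tab$label)), rep(50L, 4))
  expect_equal(sort(unique(tab$label)), 0:3)
  # reproducibility
  expect_identical(tab, generateFeatureTable(nPerClass = 50, nClasses = 4,
                                             seed = 2))
})

test_that("class separation controls attainable accuracy", {
  # separation 0: a nearest-centroid rule is at chance (1/4), checked over
  # 5 seeds with a binomial tolerance
  accs0 <- vapply(1:5, function(s) {
    tab <- generateFeatureTable(nPerClass = 60, classSeparation = 0, seed = s)
    sp <- splitDataset(tab, seed = s)
    Xtr <- as.matrix(sp$train[setdiff(names(sp$train), "label")])
    Xte <- as.matrix(sp$test[setdiff(names(sp$test), "label")])
    cent <- sapply(0:3, function(k) colMeans(Xtr[sp$train$label == k, ]))
    pred <- apply(Xte, 1, function(x) which.min(colSums((x - cent)^2)) - 1)
    mean(pred == sp$test$label)
  }, numeric(1))
  expect_lt(abs(mean(accs0) - 0.25), 0.1)

  # separation 6, no noise: nearest centroid is nearly perfect
  tab6 <- generateFeatureTable(nPerClass = 60, classSeparation = 6,
                               noiseFeatures = 0, seed = 9)
  sp6 <- splitDataset(tab6, seed = 9)
  Xtr <- as.matrix(sp6$train[setdiff(names(sp6$train), "label")])
  Xte <- as.matrix(sp6$test[setdiff(names(sp6$test), "label")])
  cent <- sapply(0:3, function(k) colMeans(Xtr[sp6$train$label == k, ]))
  pred <- apply(Xte, 1, function(x) which.min(colSums((x - cent)^2)) - 1)
  expect_gt(mean(pred == sp6$test$label), 0.99)
})
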