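test_that("stratified split is disjoint, exhaustive and reproducible", {
  tab <- generateFeatureTable(nPerClass = 25, seed = 1)
  sp <- splitDataset(tab, 0.2, seed = 1)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 20L)
  expect_equal(as.vector(table(sp$test$label)), rep(5L, 4))
  # class proportions preserved within 2%
  expect_true(all(abs(prop.table(table(sp$train$label)) - 0.25) < 0.02))
  sp2 <- splitDataset(tab, 0.2, seed = 1)
  expect_identical(sp, sp2)
  bad <- tab[c(1, 26, 51, 76, 77), ]
  expect_error(splitDataset(bad, seed = 1), "at least 2 rows")
})

test_that("confusion-matrix metrics match direct formula evaluation", {
  perfect <- diag(c(5L, 7L, 3L))
  m <- metricsFromConfusion(perfect)
  expect_equal(m$acc, 1); expect_equal(m$mcc, 1); expect_equal(m$f1, 1)

  # binary TP=TN=FP=FN=1
  m2 <- metricsFromConfusion(matrix(c(1, 1, 1, 1), 2))
  expect_equal(m2$acc, 0.5)
  expect_equal(m2$mcc, 0)
  expect_equal(m2$f1, 0.5)

  # binary case reduces to the classic MCC/F1 formulas
  cm <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)  # TP=8 FN=2 FP=3 TN=7
  m3 <- metricsFromConfusion(cm)
  tp <- 8; fn <- 2; fp <- 3; tn <- 7
  expect_equal(m3$mcc, (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  expect_equal(m3$acc, (tp + tn) / 20)

  # random 4x4 matrices against an independent covariance-form oracle
  set.seed(12)
  for (i in 1:20) {
    cm4 <- matrix(sample(0:9, 16, replace = TRUE), 4)
    if (sum(cm4) == 0) next
    m4 <- metricsFromConfusion(cm4)
    s <- sum(cm4)
    # independent oracle: expand the matrix to instance-level label pairs,
    # build one-hot indicators and take the summed-covariance correlation
    yt <- rep(rep(1:4, each = 4), as.vector(t(cm4)))   # true labels
    yp <- rep(rep(1:4, times = 4), as.vector(t(cm4)))  # predicted labels
    Tm <- sapply(1:4, function(k) as.numeric(yt == k))
    Pm <- sapply(1:4, function(k) as.numeric(yp == k))
    cv <- function(a, b) mean(a * b) - mean(a) * mean(b)
    num <- sum(vapply(1:4, function(k) cv(Tm[, k], Pm[, k]), numeric(1)))
    den <- sqrt(sum(vapply(1:4, function(k) cv(Tm[, k], Tm[, k]),
                           numeric(1))) *
                sum(vapply(1:4, function(k) cv(Pm[, k], Pm[, k]),
                           numeric(1))))
    expect_equal(m4$mcc, if (den > 0) num / den else 0, tolerance = 1e-12)
    expect_gte(m4$mcc, -1); expect_lte(m4$mcc, 1)
    expect_equal(m4$acc, sum(diag(cm4)) / s)
    # consistent label permutation leaves acc/mcc/macro-F1 unchanged
    p <- sample(4)
    mp <- metricsFromConfusion(cm4[p, p])
    expect_equal(mp$acc, m4$acc)
    expect_equal(mp$mcc, m4$mcc)
    expect_equal(mp$f1, m4$f1)
  }
  expect_error(metricsFromConfusion(matrix(0, 2, 2)), "non-empty")
})

test_that("macro AUC is 1 for perfect ranking and ~0.5 for random scores", {
  y <- rep(0:1, each = 20)
  perfect <- cbind(c(rep(1, 20), rep(0, 20)), c(rep(0, 20), rep(1, 20)))
  expect_equal(macroAUC(y, perfect), 1)
  set.seed(5)
  rnd <- matrix(runif(80), 40, 2)
  expect_lt(abs(macroAUC(y, rnd) - 0.5), 0.2)
})

test_that("accuracy-threshold selection reproduces the published member sets", {
  acc <- publishedTestAccuracies()
  s90 <- selectByAccuracy(acc, 90)
  expect_identical(selectedMembers(s90), c("KNN", "SVC", "DT", "RF", "XGB"))
  s93 <- selectByAccuracy(acc, 93)
  expect_identical(selectedMembers(s93), c("DT", "RF", "XGB"))
  s95 <- selectByAccuracy(acc, 95)
  expect_identical(selectedMembers(s95), c("RF", "XGB"))
  expect_error(selectByAccuracy(acc, 100), "no member")
  # strictly-greater rule: a member exactly at the threshold is excluded
  expect_identical(selectedMembers(selectByAccuracy(c(RF = 90, DT = 90.01),
                                                    90)), "DT")
})

test_that("the bank trains all members; accuracy tracks class separation", {
  tab <- generateFeatureTable(nPerClass = 40, classSeparation = 6,
                              noiseFeatures = 4, seed = 3)
  sp <- splitDataset(tab, seed = 3)
  norm <- minmaxNormalize(sp$train)
  testN <- applyNormalization(sp$test, norm$ranges)
  bank <- trainBank(norm$table, testN, modelBankConfig(seed = 3))
  met <- bankMetrics(bank)
  expect_equal(nrow(met), 11L)
  expect_true(all(met$test_acc >= 0 & met$test_acc <= 100))
  # a separable table is easy for the tree-based members
  trees <- met$test_acc[met$model %in% c("DT", "RF", "XGB")]
  expect_true(all(trees > 95))
  # confusion row sums equal class supports
  cm <- bankConfusions(bank)$RF
  expect_equal(unname(rowSums(cm)), as.vector(table(testN$label)))

  # chance-level data: all members near 25%
  tab0 <- generateFeatureTable(nPerClass = 40, classSeparation = 0, seed = 4)
  sp0 <- splitDataset(tab0, seed = 4)
  n0 <- minmaxNormalize(sp0$train)
  bank0 <- trainBank(n0$table, applyNormalization(sp0$test, n0$ranges),
                     modelBankConfig(seed = 4))
  expect_true(all(bankMetrics(bank0)$test_acc < 60))
  expect_lt(abs(mean(bankMetrics(bank0)$test_acc) - 25), 15)
  # reproducibility of a member fit under the fixed seed
  bankR <- trainBank(norm$table, testN,
                     modelBankConfig(members = "RF", seed = 3))
  expect_identical(bankMetrics(bankR)$test_acc,
                   met$test_acc[met$model == "RF"])
})

test_that("stacking matches single members and excels on separable data", {
  tab <- generateFeatureTable(nPerClass = 40, classSeparation = 6,
                              noiseFeatures = 4, seed = 5)
  sp <- splitDataset(tab, seed = 5)
  norm <- minmaxNormalize(sp$train)
  testN <- applyNormalization(sp$test, norm$ranges)
  cfg <- modelBankConfig(seed = 5, cvFolds = 5)

  # single-member stack within 2 points of the member alone
  bank <- trainBank(norm$table, testN, modelBankConfig(members = "RF",
                                                       seed = 5))
  single <- trainStacked(norm$table, testN,
                         new("EnsembleSpec", accuracyThreshold = 0,
                             members = "RF", metaLearner = "logistic"), cfg)
  expect_lte(abs(single$metrics$test_acc -
                   bankMetrics(bank)$test_acc), 2)

  st <- trainStacked(norm$table, testN,
                     new("EnsembleSpec", accuracyThreshold = 95,
                         members = c("RF", "XGB"), metaLearner = "logistic"),
                     cfg)
  expect_gte(st$metrics$test_acc, 95)
  # predictions are valid labels for every test row
  probs <- predictStacked(st$model, testN)
  expect_equal(dim(probs), c(nrow(testN), 4L))
  expect_true(all(max.col(probs) %in% 1:4))
  expect_equal(rowSums(probs), rep(1, nrow(testN)), tolerance = 1e-6)
})

test_that("every selection method finds planted informative features", {
  # 2 informative + 14 noise columns, checked across 5 seeds
  for (s in 1:5) {
    tab <- generateFeatureTable(nPerClass = 30, classSeparation = 4,
                                nFeatures = 16, noiseFeatures = 14, seed = s)
    norm <- minmaxNormalize(tab)$table
    informative <- mammocadFeatureNames()[1:2]
    for (m in c("rf_importance", "univariate", "correlation", "wrapper")) {
      sel <- selectFeatures(norm, m, k = 4, seed = s)
      expect_true(all(informative %in% sel$selected),
                  label = sprintf("%s seed %d informative found", m, s))
    }
  }
  # monotone: raising a threshold never keeps more features
  tab <- generateFeatureTable(nPerClass = 30, classSeparation = 4, seed = 9)
  norm <- minmaxNormalize(tab)$table
  nLow <- length(selectFeatures(norm, "rf_importance", threshold = 0.01,
                                seed = 9)$selected)
  nHigh <- length(selectFeatures(norm, "rf_importance", threshold = 0.06,
                                 seed = 9)$selected)
  expect_lte(nHigh, nLow)
  # threshold 0 keeps all 16
  expect_length(selectFeatures(norm, "rf_importance", threshold = 0,
                               seed = 9)$selected, 16L)
  # pca projects onto the requested number of components
  selp <- selectFeatures(norm, "pca", k = 5, seed = 9)
  red <- applyFeatureSelection(selp, norm)
  expect_identical(setdiff(names(red), "label"), paste0("PC", 1:5))
})

test_that("k-fold sweep covers its grid and supports leave-one-out", {
  tab <- generateFeatureTable(nPerClass = 30, classSeparation = 6,
                              noiseFeatures = 4, seed = 6)
  norm <- minmaxNormalize(tab)$table
  sw <- kfoldSweep(norm, "DT", kValues = c(3L, 10L, 30L),
                   config = modelBankConfig(seed = 6))
  expect_equal(sw$k, c(3L, 10L, 30L))
  expect_true(all(sw$mean_acc >= 0 & sw$mean_acc <= 100))
  # tiny table leave-one-out runs without error
  tiny <- generateFeatureTable(nPerClass = 3, nClasses = 2,
                               classSeparation = 6, noiseFeatures = 0,
                               nFeatures = 4, seed = 7)
  tinyN <- minmaxNormalize(tiny)$table
  swLoo <- kfoldSweep(tinyN, "GNB", kValues = nrow(tinyN),
                      config = modelBankConfig(seed = 7))
  expect_equal(swLoo$k, 6L)
  expect_error(kfoldSweep(norm, "DT", kValues = 500L), "kValues")
})
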