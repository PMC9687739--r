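#' @include AllClasses.R learners.R features.R
NULL

#' Classifier-bank configuration
#'
#' The eleven-member bank: K nearest neighbours (KNN), RBF-kernel support
#' vector classification (SVC), decision tree (DT), random forest (RF),
#' multilayer perceptron (MLP), AdaBoost (AB), gradient-boosted trees (XGB),
#' Gaussian naive Bayes (GNB), linear support vector machine (SVM),
#' stochastic-gradient-descent logistic classifier (SGD) and multinomial
#' logistic regression (LR). Member order is the bank's declared order and is
#' preserved by every selection rule.
#'
#' @param members character vector of member names (default: all eleven).
#' @param cvFolds folds used for the stacking out-of-fold probabilities
#'   (default 10).
#' @param seed integer seed fixed before every training run.
#' @param params named list of per-member hyperparameter overrides.
#' @return a list with class \code{mammocadBankConfig}.
#' @examples
#' modelBankConfig(cvFolds = 5)$members
#' @export
modelBankConfig <- function(members = .BANK_MEMBERS, cvFolds = 10L,
                            seed = 1L, params = list()) {
  .stopIfNot(all(members %in% .BANK_MEMBERS),
             paste("members must be among:",
                   paste(.BANK_MEMBERS, collapse = ", ")))
  structure(list(members = members, cvFolds = as.integer(cvFolds),
                 seed = as.integer(seed), params = params),
            class = "mammocadBankConfig")
}

#' Stratified train/test split
#'
#' Splits a labelled feature table into disjoint, exhaustive train and test
#' sets, stratified by class; per-class test sizes are within one row of the
#' exact fraction. Reproducible under a fixed seed.
#'
#' @param table feature data.frame with a \code{label} column.
#' @param testFraction held-out fraction (default 0.2, the 80:20 split).
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} data.frames.
#' @examples
#' tab <- generateFeatureTable(nPerClass = 25, seed = 1)
#' sapply(splitDataset(tab, seed = 1), nrow)
#' @export
splitDataset <- function(table, testFraction = 0.2, seed = 1L) {
  .stopIfNot(nrow(table) >= 5L, "at least 5 rows are required")
  .stopIfNot(!is.null(table$label), "table must have a 'label' column")
  counts <- table(table$label)
  if (any(counts < 2L))
    stop("every class needs at least 2 rows to stratify", call. = FALSE)
  set.seed(seed)
  testIdx <- integer(0)
  for (cl in names(counts)) {
    rows <- which(table$label == cl)
    nTest <- round(length(rows) * testFraction)
    nTest <- min(max(nTest, 1L), length(rows) - 1L)
    testIdx <- c(testIdx, sample(rows, nTest))
  }
  list(train = table[-testIdx, , drop = FALSE],
       test = table[sort(testIdx), , drop = FALSE])
}

.xy <- function(table) {
  list(X = as.matrix(table[.featureColumns(table)]),
       y = as.integer(table$label))
}

#' Accuracy, MCC and macro F1 from a confusion matrix
#'
#' Accuracy is the trace over the total. MCC uses the multi-category
#' (covariance-form) generalisation, which reduces to the familiar binary
#' formula for a 2x2 matrix. F1 is macro-averaged over one-vs-rest
#' collapses; a class absent from both margins contributes an F1 of 0.
#'
#' @param cm square non-negative confusion matrix, rows = true classes,
#'   columns = predicted classes.
#' @return list with \code{acc}, \code{mcc}, \code{f1} (all fractions in
#'   [0, 1], mcc in [-1, 1]) and \code{perClass} (data.frame of one-vs-rest
#'   precision/recall/F1).
#' @examples
#' metricsFromConfusion(matrix(c(1, 1, 1, 1), 2))  # acc .5, mcc 0, f1 .5
#' @export
metricsFromConfusion <- function(cm) {
  cm <- as.matrix(cm)
  .stopIfNot(nrow(cm) == ncol(cm) && nrow(cm) >= 1L && sum(cm) > 0,
             "confusion matrix must be square and non-empty")
  .stopIfNot(all(cm >= 0), "confusion matrix must be non-negative")
  s <- sum(cm)
  tr <- sum(diag(cm))
  tv <- rowSums(cm)   # true-class supports
  pv <- colSums(cm)   # predicted-class totals
  acc <- tr / s
  den <- sqrt(s^2 - sum(pv^2)) * sqrt(s^2 - sum(tv^2))
  mcc <- if (den > 0) (s * tr - sum(tv * pv)) / den else 0
  K <- nrow(cm)
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    prec[k] <- if (pv[k] > 0) tp / pv[k] else 0
    rec[k] <- if (tv[k] > 0) tp / tv[k] else 0
    f1[k] <- if (2 * tp + (pv[k] - tp) + (tv[k] - tp) > 0)
      2 * tp / (2 * tp + (pv[k] - tp) + (tv[k] - tp)) else 0
  }
  list(acc = acc, mcc = mcc, f1 = mean(f1),
       perClass = data.frame(class = seq_len(K) - 1L, precision = prec,
                             recall = rec, f1 = f1))
}

#' Macro one-vs-rest AUC
#'
#' Rank-based (Mann-Whitney) AUC of each class's probability column against
#' the rest, averaged over the classes present in \code{y}.
#'
#' @param y integer labels 0..K-1.
#' @param probs n x K class-probability matrix.
#' @return the macro AUC in [0, 1].
#' @export
macroAUC <- function(y, probs) {
  K <- ncol(probs)
  aucs <- c()
  for (k in seq_len(K)) {
    pos <- y == (k - 1L)
    if (!any(pos) || all(pos)) next
    r <- rank(probs[, k])
    n1 <- sum(pos); n0 <- sum(!pos)
    aucs <- c(aucs, (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  mean(aucs)
}

.confusion <- function(y, pred, K) {
  cm <- matrix(0L, K, K, dimnames = list(true = 0:(K - 1L),
                                         pred = 0:(K - 1L)))
  for (i in seq_along(y)) cm[y[i] + 1L, pred[i] + 1L] <-
      cm[y[i] + 1L, pred[i] + 1L] + 1L
  cm
}

.evalSplit <- function(yTrain, pTrain, yTest, pTest, K) {
  predTr <- max.col(pTrain, ties.method = "first") - 1L
  predTe <- max.col(pTest, ties.method = "first") - 1L
  mTr <- metricsFromConfusion(.confusion(yTrain, predTr, K))
  cmTe <- .confusion(yTest, predTe, K)
  mTe <- metricsFromConfusion(cmTe)
  list(row = data.frame(train_acc = 100 * mTr$acc, train_mcc = 100 * mTr$mcc,
                        train_f1 = 100 * mTr$f1, test_acc = 100 * mTe$acc,
                        test_mcc = 100 * mTe$mcc, test_f1 = 100 * mTe$f1,
                        auc = 100 * macroAUC(yTest, pTest)),
       confusion = cmTe)
}

#' Train and evaluate the classifier bank
#'
#' Fits every configured member on the (normalised) training table and
#' evaluates train/test accuracy, MCC, macro F1 and macro AUC. Training is
#' reproducible: the configured seed is set before each member's fit.
#'
#' @param train,test feature data.frames with \code{label} columns (use
#'   [minmaxNormalize()] / [applyNormalization()] first).
#' @param config a [modelBankConfig()].
#' @return an [EnsembleReport-class] with one metrics row per member.
#' @examples
#' tab <- generateFeatureTable(nPerClass = 15, classSeparation = 6, seed = 1)
#' sp <- splitDataset(tab, seed = 1)
#' \donttest{rep <- trainBank(sp$train, sp$test,
#'   modelBankConfig(members = c("DT", "GNB")))}
#' @export
trainBank <- function(train, test, config = modelBankConfig()) {
  tr <- .xy(train); te <- .xy(test)
  .stopIfNot(length(unique(tr$y)) >= 2L,
             "training set must contain at least two classes")
  K <- max(c(tr$y, te$y)) + 1L
  rows <- list(); confusions <- list(); models <- list()
  for (m in config$members) {
    set.seed(config$seed)
    fit <- .fitLearner(m, tr$X, tr$y, K, config$params[[m]] %||% list())
    ev <- .evalSplit(tr$y, .predictLearner(fit, tr$X),
                     te$y, .predictLearner(fit, te$X), K)
    rows[[m]] <- cbind(data.frame(model = m), ev$row)
    confusions[[m]] <- ev$confusion
    models[[m]] <- fit
  }
  new("EnsembleReport", metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
      confusions = confusions, models = models,
      config = unclass(config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select ensemble members by test accuracy
#'
#' Keeps the bank members whose test accuracy strictly exceeds the threshold
#' (the "accuracies above X percent" rule), preserving the bank's declared
#' order, and pairs them with the fixed logistic-regression meta-learner.
#'
#' @param report an [EnsembleReport-class], or a named numeric vector of
#'   test accuracies in percent (e.g. a published accuracy column).
#' @param threshold accuracy threshold in percent (default 90).
#' @return an [EnsembleSpec-class]; an empty selection is an error.
#' @examples
#' acc <- c(KNN = 92.82, SVC = 92.82, DT = 94.62, RF = 95.91, MLP = 70.61,
#'          AB = 54.39, XGB = 95.40, GNB = 43.97, SVM = 36.96, SGD = 40.54,
#'          LR = 42.90)
#' selectedMembers(selectByAccuracy(acc, 93))
#' @export
selectByAccuracy <- function(report, threshold = 90) {
  if (is(report, "EnsembleReport")) {
    acc <- report@metrics$test_acc
    names(acc) <- report@metrics$model
  } else {
    .stopIfNot(is.numeric(report) && !is.null(names(report)),
               "report must be an EnsembleReport or a named numeric vector")
    acc <- report
  }
  ordered <- intersect(.BANK_MEMBERS, names(acc))
  sel <- ordered[acc[ordered] > threshold]
  if (length(sel) == 0L)
    stop(sprintf("no member exceeds %g%% test accuracy", threshold),
         call. = FALSE)
  new("EnsembleSpec", accuracyThreshold = threshold, members = sel,
      metaLearner = "logistic")
}

.stratifiedFolds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    rows <- which(y == cl)
    rows <- rows[sample.int(length(rows))]
    folds[rows] <- rep_len(seq_len(k), length(rows))
  }
  folds
}

# Out-of-fold class probabilities for one member.
.oofProbs <- function(member, X, y, K, folds, params) {
  P <- matrix(0, nrow(X), K)
  for (f in sort(unique(folds))) {
    inTr <- folds != f
    fit <- .fitLearner(member, X[inTr, , drop = FALSE], y[inTr], K, params)
    P[!inTr, ] <- .predictLearner(fit, X[!inTr, , drop = FALSE])
  }
  P
}

#' Train a stacking ensemble
#'
#' Stacks the specified members: each member's cross-validated out-of-fold
#' class probabilities on the training set form the meta-features on which a
#' multinomial logistic-regression meta-learner is fitted; the members are
#' then refitted on the full training set to produce test meta-features.
#'
#' @param train,test normalised feature data.frames with \code{label}.
#' @param spec an [EnsembleSpec-class] (e.g. from [selectByAccuracy()]).
#' @param config a [modelBankConfig()]; \code{cvFolds} controls the
#'   out-of-fold split.
#' @return list with \code{metrics} (one-row data.frame named after the
#'   stack), \code{confusion}, \code{model} (reusable for prediction via
#'   [predictStacked()]).
#' @export
trainStacked <- function(train, test, spec, config = modelBankConfig()) {
  stopifnot(is(spec, "EnsembleSpec"))
  validObject(spec)
  tr <- .xy(train); te <- .xy(test)
  K <- max(c(tr$y, te$y)) + 1L
  set.seed(config$seed)
  folds <- .stratifiedFolds(tr$y, min(config$cvFolds, min(table(tr$y))))
  Ztr <- NULL; members <- list()
  for (m in spec@members) {
    set.seed(config$seed)
    Ztr <- cbind(Ztr, .oofProbs(m, tr$X, tr$y, K, folds,
                                config$params[[m]] %||% list()))
    set.seed(config$seed)
    members[[m]] <- .fitLearner(m, tr$X, tr$y, K,
                                config$params[[m]] %||% list())
  }
  Zte <- do.call(cbind, lapply(members, function(m) .predictLearner(m, te$X)))
  meta <- glmnet::glmnet(Ztr, factor(tr$y, levels = 0:(K - 1L)),
                         family = "multinomial", alpha = 0,
                         lambda = c(1, 0.1, 0.01, 1e-3))
  pTr <- matrix(predict(meta, Ztr, s = 1e-3, type = "response")[, , 1L],
                nrow(Ztr), K)
  pTe <- matrix(predict(meta, Zte, s = 1e-3, type = "response")[, , 1L],
                nrow(Zte), K)
  ev <- .evalSplit(tr$y, pTr, te$y, pTe, K)
  name <- paste(spec@members, collapse = "-")
  list(metrics = cbind(data.frame(model = name), ev$row),
       confusion = ev$confusion,
       model = structure(list(members = members, meta = meta, K = K,
                              spec = spec), class = "mammocadStack"))
}

#' Predict with a fitted stacking ensemble
#'
#' @param model the \code{model} component returned by [trainStacked()].
#' @param table feature data.frame (same normalisation as training).
#' @return n x K matrix of class probabilities.
#' @export
predictStacked <- function(model, table) {
  stopifnot(inherits(model, "mammocadStack"))
  X <- as.matrix(table[.featureColumns(table)])
  Z <- do.call(cbind, lapply(model$members, function(m) .predictLearner(m, X)))
  matrix(predict(model$meta, Z, s = 1e-3, type = "response")[, , 1L],
         nrow(Z), model$K)
}

#' Feature selection
#'
#' Five selection strategies over a normalised training table:
#' \describe{
#'   \item{rf_importance}{keep features whose impurity-based random-forest
#'     importance (normalised to sum 1) is at least \code{threshold}.}
#'   \item{univariate}{top-\code{k} features by one-way ANOVA F score
#'     against the class label.}
#'   \item{correlation}{keep features whose absolute Pearson correlation
#'     with the integer class label is at least \code{threshold}.}
#'   \item{pca}{the top-\code{k} principal components (fitted on the
#'     training features only); selection then denotes components, and
#'     [applyFeatureSelection()] projects tables onto them.}
#'   \item{wrapper}{greedy sequential forward selection maximising
#'     cross-validated accuracy of a fast learner, stopping when the best
#'     gain falls below \code{threshold}.}
#' }
#'
#' @param train normalised feature data.frame with \code{label}.
#' @param method one of the five method names.
#' @param threshold method-specific threshold (rf_importance, correlation,
#'   wrapper).
#' @param k number of features/components (univariate, pca).
#' @param learner bank member used inside the wrapper (default "DT").
#' @param cvFolds wrapper cross-validation folds (default 5).
#' @param seed RNG seed.
#' @return list with class \code{mammocadFeatSel}: \code{method},
#'   \code{selected} (names), \code{scores} (per-feature criterion), and for
#'   pca the fitted rotation. Empty selections are an error.
#' @examples
#' tab <- generateFeatureTable(nPerClass = 20, classSeparation = 4, seed = 2)
#' selectFeatures(tab, "univariate", k = 4)$selected
#' @export
selectFeatures <- function(train,
                           method = c("rf_importance", "univariate",
                                      "correlation", "pca", "wrapper"),
                           threshold = NULL, k = NULL, learner = "DT",
                           cvFolds = 5L, seed = 1L) {
  method <- match.arg(method)
  tr <- .xy(train)
  feats <- .featureColumns(train)
  K <- length(unique(tr$y))
  set.seed(seed)
  out <- list(method = method, threshold = threshold, k = k)
  if (method == "rf_importance") {
    threshold <- threshold %||% 0.045
    imp <- .rfImportance(tr$X, tr$y, max(tr$y) + 1L)
    names(imp) <- feats
    sel <- feats[imp >= threshold]
    out$scores <- imp
  } else if (method == "univariate") {
    k <- k %||% 12L
    Fs <- vapply(seq_along(feats), function(j)
      .anovaF(tr$X[, j], tr$y), numeric(1))
    names(Fs) <- feats
    sel <- feats[order(Fs, decreasing = TRUE)[seq_len(min(k, length(feats)))]]
    sel <- feats[feats %in% sel]           # keep original column order
    out$scores <- Fs
  } else if (method == "correlation") {
    threshold <- threshold %||% 0.01
    r <- abs(suppressWarnings(
      apply(tr$X, 2L, stats::cor, y = as.numeric(tr$y))))
    r[is.na(r)] <- 0
    names(r) <- feats
    sel <- feats[r >= threshold]
    out$scores <- r
  } else if (method == "pca") {
    k <- k %||% 10L
    pc <- stats::prcomp(tr$X, center = TRUE, scale. = FALSE)
    k <- min(k, ncol(pc$rotation))
    sel <- colnames(pc$rotation)[seq_len(k)]
    out$center <- pc$center
    out$rotation <- pc$rotation[, seq_len(k), drop = FALSE]
    out$scores <- pc$sdev^2 / sum(pc$sdev^2)
  } else {                                 # wrapper
    threshold <- threshold %||% 0.01
    sel <- character(0)
    remaining <- feats
    bestAcc <- 0
    folds <- .stratifiedFolds(tr$y, min(cvFolds, min(table(tr$y))))
    cvAcc <- function(cols) {
      acc <- 0
      for (f in sort(unique(folds))) {
        inTr <- folds != f
        fit <- .fitLearner(learner, tr$X[inTr, cols, drop = FALSE],
                           tr$y[inTr], max(tr$y) + 1L, list())
        p <- .predictLearner(fit, tr$X[!inTr, cols, drop = FALSE])
        acc <- acc + sum((max.col(p, ties.method = "first") - 1L) ==
                           tr$y[!inTr])
      }
      acc / length(tr$y)
    }
    repeat {
      if (length(remaining) == 0L) break
      accs <- vapply(remaining, function(f) cvAcc(c(sel, f)), numeric(1))
      gain <- max(accs) - bestAcc
      if (length(sel) > 0L && gain < threshold) break
      pick <- remaining[which.max(accs)]
      sel <- c(sel, pick)
      remaining <- setdiff(remaining, pick)
      bestAcc <- max(accs)
    }
    sel <- feats[feats %in% sel]
    out$cvAccuracy <- bestAcc
  }
  if (length(sel) == 0L)
    stop(sprintf("feature selection '%s' selected nothing", method),
         call. = FALSE)
  out$threshold <- threshold
  out$k <- k
  out$selected <- sel
  structure(out, class = "mammocadFeatSel")
}

.anovaF <- function(x, y) {
  mu <- mean(x)
  K <- length(unique(y))
  n <- length(x)
  ssb <- 0; ssw <- 0
  for (cl in unique(y)) {
    xi <- x[y == cl]
    ssb <- ssb + length(xi) * (mean(xi) - mu)^2
    ssw <- ssw + sum((xi - mean(xi))^2)
  }
  if (ssw <= 0) return(Inf)
  (ssb / (K - 1)) / (ssw / (n - K))
}

# Impurity-based forest importance: total weighted Gini gain per feature,
# accumulated over a forest and normalised to sum 1.
.rfImportance <- function(X, y, K, nTree = 100L) {
  p <- ncol(X)
  imp <- numeric(p)
  n <- nrow(X)
  mtry <- max(1L, floor(sqrt(p)))
  for (t in seq_len(nTree)) {
    rows <- sample.int(n, n, replace = TRUE)
    tr <- .grow_class_tree(X, y, rep(1, n), K, 16L, 2L, mtry, rows)
    gains <- .treeGains(tr, X, y, rows, K)
    imp <- imp + gains
  }
  if (sum(imp) > 0) imp / sum(imp) else imp
}

# Recompute each internal node's weighted impurity decrease by replaying the
# tree on its training rows.
.treeGains <- function(tree, X, y, rows, K) {
  p <- ncol(X)
  gains <- numeric(p)
  recurse <- function(node, idx) {
    f <- tree$feature[node + 1L]
    if (f < 0 || length(idx) == 0L) return(invisible())
    gini <- function(ys) {
      if (length(ys) == 0L) return(0)
      pr <- tabulate(ys + 1L, nbins = K) / length(ys)
      1 - sum(pr^2)
    }
    goL <- X[idx, f + 1L] <= tree$threshold[node + 1L]
    gL <- gini(y[idx[goL]]); gR <- gini(y[idx[!goL]])
    dec <- length(idx) * gini(y[idx]) -
      (sum(goL) * gL + sum(!goL) * gR)
    gains[f + 1L] <<- gains[f + 1L] + max(dec, 0)
    recurse(tree$left[node + 1L], idx[goL])
    recurse(tree$right[node + 1L], idx[!goL])
  }
  recurse(0L, rows)
  gains
}

#' Apply a fitted feature selection to a table
#'
#' Subsets the selected feature columns (or projects onto the fitted
#' principal components for pca), keeping \code{label}/\code{image_id}.
#'
#' @param sel a \code{mammocadFeatSel} from [selectFeatures()].
#' @param table feature data.frame.
#' @return the reduced data.frame.
#' @export
applyFeatureSelection <- function(sel, table) {
  stopifnot(inherits(sel, "mammocadFeatSel"))
  keepMeta <- intersect(c("image_id", "label"), names(table))
  if (sel$method == "pca") {
    X <- as.matrix(table[.featureColumns(table)])
    Z <- sweep(X, 2L, sel$center) %*% sel$rotation
    out <- as.data.frame(Z)
  } else {
    out <- table[sel$selected]
  }
  cbind(out, table[keepMeta])
}

#' K-fold robustness sweep
#'
#' Stratified K-fold cross-validation of a single member or a stacking
#' ensemble for each K in \code{kValues} (default: the twelve values spanning
#' 3 to 30), reporting the mean and spread of the per-fold test accuracy.
#' K may reach the number of rows (leave-one-out); the only hard requirement
#' is that every fold's training rows still contain every class.
#'
#' @param table normalised feature data.frame with \code{label}.
#' @param model a bank member name (e.g. "DT") or an [EnsembleSpec-class].
#' @param kValues integer vector of fold counts.
#' @param config a [modelBankConfig()] (seed, member parameters; the inner
#'   stacking folds are capped at 5 for tractability).
#' @return data.frame with columns \code{k}, \code{mean_acc}, \code{sd_acc},
#'   \code{min_acc}, \code{max_acc} (accuracies in percent).
#' @export
kfoldSweep <- function(table, model = "DT",
                       kValues = c(3L, 4L, 5L, 7L, 10L, 12L, 15L, 18L, 20L,
                                   22L, 25L, 30L),
                       config = modelBankConfig()) {
  tab <- .xy(table)
  K <- max(tab$y) + 1L
  .stopIfNot(all(kValues >= 2L & kValues <= nrow(table)),
             "kValues must lie in [2, nrow(table)]")
  out <- data.frame()
  for (kv in kValues) {
    set.seed(config$seed + kv)
    folds <- .stratifiedFolds(tab$y, kv)
    accs <- numeric(0)
    for (f in sort(unique(folds))) {
      inTr <- folds != f
      if (length(unique(tab$y[inTr])) < K)
        stop(sprintf("K = %d leaves a training fold without all classes", kv),
             call. = FALSE)
      trainTab <- table[inTr, , drop = FALSE]
      testTab <- table[!inTr, , drop = FALSE]
      if (is(model, "EnsembleSpec")) {
        cfg <- config
        cfg$cvFolds <- min(5L, config$cvFolds)
        st <- trainStacked(trainTab, testTab, model, cfg)
        accs <- c(accs, st$metrics$test_acc)
      } else {
        set.seed(config$seed)
        fit <- .fitLearner(model, tab$X[inTr, , drop = FALSE], tab$y[inTr],
                           K, config$params[[model]] %||% list())
        p <- .predictLearner(fit, tab$X[!inTr, , drop = FALSE])
        accs <- c(accs, 100 * mean((max.col(p, ties.method = "first") - 1L)
                                   == tab$y[!inTr]))
      }
    }
    out <- rbind(out, data.frame(k = kv, mean_acc = mean(accs),
                                 sd_acc = if (length(accs) > 1) sd(accs) else 0,
                                 min_acc = min(accs), max_acc = max(accs)))
  }
  out
}
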