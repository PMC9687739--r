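# Internal implementations of the eleven-member classifier bank. The
# environment provides no tree/SVM/neural-network packages, so compact
# versions live here: CART kernels are compiled (see src/trees.cpp), the
# remaining learners are small vectorised R. Every learner exposes the same
# contract: .fitLearner() returns an object, .predictLearner() returns an
# n x K class-probability matrix (margin-based members return softmax
# pseudo-probabilities, documented per learner).

.BANK_MEMBERS <- c("KNN", "SVC", "DT", "RF", "MLP", "AB", "XGB", "GNB",
                   "SVM", "SGD", "LR")

.softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

.onehot <- function(y, K) {
  Y <- matrix(0, length(y), K)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

.defaultParams <- function() list(
  DT = list(maxDepth = 16L, minSplit = 2L),
  RF = list(nTree = 100L, maxDepth = 16L, minSplit = 2L),
  AB = list(nRounds = 60L, maxDepth = 2L),
  XGB = list(nRounds = 60L, eta = 0.3, maxDepth = 3L, lambda = 1,
             minChildWeight = 1),
  KNN = list(k = 5L),
  MLP = list(hidden = 32L, epochs = 300L, lr = 0.01),
  GNB = list(varSmoothing = 1e-9),
  SGD = list(epochs = 50L, lr0 = 0.5, l2 = 1e-4, batch = 16L),
  SVM = list(lambda = 1e-3, epochs = 50L),
  SVC = list(lambda = 1e-3, scoreScale = 10),
  LR = list(lambdaPath = c(1, 0.1, 0.01, 1e-3, 1e-4)))

.fitLearner <- function(name, X, y, K, params = list()) {
  p <- utils::modifyList(.defaultParams()[[name]], params)
  obj <- switch(name,
    DT = list(tree = .grow_class_tree(X, y, rep(1, nrow(X)), K,
                                      p$maxDepth, p$minSplit, ncol(X))),
    RF = {
      n <- nrow(X)
      mtry <- max(1L, floor(sqrt(ncol(X))))
      trees <- lapply(seq_len(p$nTree), function(i) {
        rows <- sample.int(n, n, replace = TRUE)
        .grow_class_tree(X, y, rep(1, n), K, p$maxDepth, p$minSplit, mtry,
                         rows)
      })
      list(trees = trees)
    },
    AB = .fitAdaBoost(X, y, K, p),
    XGB = .fitGradBoost(X, y, K, p),
    KNN = list(X = X, y = y, k = p$k),
    MLP = .fitMLP(X, y, K, p),
    GNB = .fitGNB(X, y, K, p),
    SGD = .fitSoftmaxSGD(X, y, K, p),
    SVM = .fitLinearSVM(X, y, K, p),
    SVC = .fitKernelSVC(X, y, K, p),
    LR = {
      pad <- ncol(X) < 2L       # glmnet requires at least two columns
      Xf <- if (pad) cbind(X, 0) else X
      fit <- glmnet::glmnet(Xf, factor(y, levels = 0:(K - 1L)),
                            family = "multinomial", alpha = 0,
                            lambda = p$lambdaPath)
      list(fit = fit, s = min(p$lambdaPath), pad = pad)
    },
    stop(sprintf("unknown bank member '%s'", name)))
  structure(c(obj, list(member = name, K = K)), class = "mammocadLearner")
}

.predictLearner <- function(obj, X) {
  K <- obj$K
  P <- switch(obj$member,
    DT = .predict_class_tree(obj$tree, X),
    RF = {
      acc <- matrix(0, nrow(X), K)
      for (tr in obj$trees) acc <- acc + .predict_class_tree(tr, X)
      acc / length(obj$trees)
    },
    AB = {
      S <- matrix(0, nrow(X), K)
      for (i in seq_along(obj$trees)) {
        pr <- .predict_class_tree(obj$trees[[i]], X)
        hard <- max.col(pr, ties.method = "first")
        S[cbind(seq_len(nrow(X)), hard)] <-
          S[cbind(seq_len(nrow(X)), hard)] + obj$alpha[i]
      }
      S / pmax(sum(obj$alpha), 1e-12)
    },
    XGB = {
      S <- matrix(obj$base, nrow(X), K, byrow = TRUE)
      for (m in seq_along(obj$trees)) {
        for (k in seq_len(K)) {
          S[, k] <- S[, k] + obj$eta *
            .predict_grad_tree(obj$trees[[m]][[k]], X)
        }
      }
      .softmax(S)
    },
    KNN = .predictKNN(obj, X),
    MLP = .predictMLP(obj, X),
    GNB = .predictGNB(obj, X),
    SGD = .softmax(cbind(1, X) %*% obj$W),
    SVM = .softmax(2 * (cbind(1, X) %*% obj$W)),
    SVC = {
      D2 <- outer(rowSums(X^2), rowSums(obj$X^2), "+") - 2 * X %*% t(obj$X)
      Km <- exp(-obj$gamma * pmax(D2, 0))
      .softmax(obj$scoreScale * (Km %*% obj$alpha))
    },
    LR = {
      Xf <- if (isTRUE(obj$pad)) cbind(X, 0) else X
      pr <- predict(obj$fit, Xf, s = obj$s, type = "response")
      matrix(pr[, , 1L], nrow(X), K)
    })
  P <- pmax(P, 0)
  sweep(P, 1L, pmax(rowSums(P), 1e-12), "/")
}

# AdaBoost, multi-class SAMME over shallow weighted CART stumps.
.fitAdaBoost <- function(X, y, K, p) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list(); alpha <- numeric()
  for (m in seq_len(p$nRounds)) {
    tr <- .grow_class_tree(X, y, w, K, p$maxDepth, 2L, ncol(X))
    pred <- max.col(.predict_class_tree(tr, X), ties.method = "first") - 1L
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    a <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(a * (pred != y))
    w <- w / sum(w)
    trees[[m]] <- tr
    alpha[m] <- a
    if (err < 1e-10) break
  }
  list(trees = trees, alpha = alpha)
}

# Gradient boosting with softmax loss and second-order trees (shrinkage and
# a regularised split objective, as in modern boosting systems).
.fitGradBoost <- function(X, y, K, p) {
  n <- nrow(X)
  Y <- .onehot(y, K)
  base <- rep(0, K)
  S <- matrix(0, n, K)
  trees <- vector("list", p$nRounds)
  for (m in seq_len(p$nRounds)) {
    P <- .softmax(S)
    round <- vector("list", K)
    for (k in seq_len(K)) {
      g <- P[, k] - Y[, k]
      h <- pmax(P[, k] * (1 - P[, k]), 1e-6)
      tr <- .grow_grad_tree(X, g, h, p$maxDepth, p$minChildWeight,
                            p$lambda, ncol(X))
      round[[k]] <- tr
      S[, k] <- S[, k] + p$eta * .predict_grad_tree(tr, X)
    }
    trees[[m]] <- round
  }
  list(trees = trees, eta = p$eta, base = base)
}

.predictKNN <- function(obj, X) {
  K <- obj$K
  D2 <- outer(rowSums(X^2), rowSums(obj$X^2), "+") - 2 * X %*% t(obj$X)
  k <- min(obj$k, ncol(D2))
  P <- matrix(0, nrow(X), K)
  for (i in seq_len(nrow(X))) {
    nb <- order(D2[i, ])[seq_len(k)]
    tab <- tabulate(obj$y[nb] + 1L, nbins = K)
    P[i, ] <- tab / k
  }
  P
}

# One-hidden-layer perceptron, tanh activation, softmax output, full-batch
# Adam on the cross-entropy.
.fitMLP <- function(X, y, K, p) {
  n <- nrow(X); d <- ncol(X); H <- p$hidden
  Y <- .onehot(y, K)
  W1 <- matrix(rnorm(d * H, sd = 1 / sqrt(d)), d, H); b1 <- rep(0, H)
  W2 <- matrix(rnorm(H * K, sd = 1 / sqrt(H)), H, K); b2 <- rep(0, K)
  ms <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0)
  vs <- ms
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  for (t in seq_len(p$epochs)) {
    A <- tanh(sweep(X %*% W1, 2L, b1, "+"))
    P <- .softmax(sweep(A %*% W2, 2L, b2, "+"))
    dS <- (P - Y) / n
    gW2 <- t(A) %*% dS; gb2 <- colSums(dS)
    dA <- dS %*% t(W2) * (1 - A^2)
    gW1 <- t(X) %*% dA; gb1 <- colSums(dA)
    gs <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(gs)) {
      ms[[nm]] <- b1m * ms[[nm]] + (1 - b1m) * gs[[nm]]
      vs[[nm]] <- b2m * vs[[nm]] + (1 - b2m) * gs[[nm]]^2
      mhat <- ms[[nm]] / (1 - b1m^t)
      vhat <- vs[[nm]] / (1 - b2m^t)
      upd <- p$lr * mhat / (sqrt(vhat) + eps)
      if (nm == "W1") W1 <- W1 - upd
      if (nm == "b1") b1 <- b1 - upd
      if (nm == "W2") W2 <- W2 - upd
      if (nm == "b2") b2 <- b2 - upd
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.predictMLP <- function(obj, X) {
  A <- tanh(sweep(X %*% obj$W1, 2L, obj$b1, "+"))
  .softmax(sweep(A %*% obj$W2, 2L, obj$b2, "+"))
}

.fitGNB <- function(X, y, K, p) {
  mus <- vars <- matrix(0, K, ncol(X))
  prior <- numeric(K)
  for (k in seq_len(K)) {
    rows <- y == (k - 1L)
    prior[k] <- mean(rows)
    Xi <- X[rows, , drop = FALSE]
    mus[k, ] <- colMeans(Xi)
    vars[k, ] <- apply(Xi, 2L, function(v) mean((v - mean(v))^2))
  }
  vars <- vars + p$varSmoothing * max(vars, 1e-12)
  list(mu = mus, var = vars, prior = pmax(prior, 1e-12))
}

.predictGNB <- function(obj, X) {
  K <- nrow(obj$mu)
  L <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    L[, k] <- log(obj$prior[k]) -
      0.5 * rowSums(sweep(sweep(X, 2L, obj$mu[k, ])^2, 2L, obj$var[k, ], "/") +
                      matrix(log(2 * pi * obj$var[k, ]), nrow(X), ncol(X),
                             byrow = TRUE))
  }
  .softmax(L)
}

# Plain stochastic gradient descent on the multinomial logistic loss,
# shuffled mini-batches, decaying step size, L2 penalty.
.fitSoftmaxSGD <- function(X, y, K, p) {
  Xb <- cbind(1, X)
  n <- nrow(Xb); d <- ncol(Xb)
  W <- matrix(0, d, K)
  Y <- .onehot(y, K)
  t <- 0
  for (e in seq_len(p$epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = p$batch)) {
      t <- t + 1
      rows <- ord[s:min(s + p$batch - 1L, n)]
      P <- .softmax(Xb[rows, , drop = FALSE] %*% W)
      G <- t(Xb[rows, , drop = FALSE]) %*%
        (P - Y[rows, , drop = FALSE]) / length(rows) + p$l2 * W
      W <- W - p$lr0 / (1 + 0.01 * t) * G
    }
  }
  list(W = W)
}

# Linear one-vs-rest SVM trained with the Pegasos subgradient scheme; class
# scores are turned into softmax pseudo-probabilities.
.fitLinearSVM <- function(X, y, K, p) {
  Xb <- cbind(1, X)
  n <- nrow(Xb); d <- ncol(Xb)
  W <- matrix(0, d, K)
  Yp <- 2 * .onehot(y, K) - 1
  t <- 0
  for (e in seq_len(p$epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      t <- t + 1
      eta <- 1 / (p$lambda * t)
      m <- Yp[i, ] * drop(Xb[i, ] %*% W)
      W <- (1 - eta * p$lambda) * W
      viol <- which(m < 1)
      if (length(viol))
        W[, viol] <- W[, viol] + eta * outer(Xb[i, ], Yp[i, viol])
    }
  }
  list(W = W)
}

# RBF-kernel classifier: kernel ridge regression on the one-hot labels
# (least-squares SVM flavour); gamma follows the usual 1/(p * var) scaling.
.fitKernelSVC <- function(X, y, K, p) {
  gamma <- 1 / (ncol(X) * max(mean(apply(X, 2L, stats::var)), 1e-12))
  D2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  Km <- exp(-gamma * pmax(D2, 0))
  alpha <- solve(Km + p$lambda * diag(nrow(X)), .onehot(y, K))
  list(X = X, alpha = alpha, gamma = gamma, scoreScale = p$scoreScale)
}
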