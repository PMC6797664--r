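# Supervised classification harness: four classifier kinds, grid search
# over the reference grids, stratified tenfold cross-validation, pooled
# confusion matrix and weighted one-vs-rest metrics.

#' Classifier configuration
#'
#' Returns a configuration list for one of the four classifier kinds.  The
#' defaults are the reference optima of the method on clinical data
#' (polynomial SVM C = 1; RBF SVM C = 1, gamma = 0.01; kNN k = 3; random
#' forest depth 8 with 50 trees), shipped as documented starting points.
#' The polynomial kernel exponent defaults to 1, matching the SMO/WEKA
#' PolyKernel setup the reference results were obtained with.
#'
#' @param kind one of \code{"svm_poly"}, \code{"svm_rbf"}, \code{"knn"},
#'   \code{"rf"}.
#' @param C,gamma SVM cost and RBF kernel width.
#' @param degree polynomial kernel exponent.
#' @param k neighbour count for kNN.
#' @param depth,nTrees tree depth (realized as \code{maxnodes = 2^depth})
#'   and forest size for RF.
#' @return named list with class \code{"classifierConfig"}.
#' @export
classifierConfig <- function(kind = c("svm_poly", "svm_rbf", "knn", "rf"),
                             C = 1, gamma = 0.01, degree = 1L, k = 3L,
                             depth = 8L, nTrees = 50L) {
  kind <- match.arg(kind)
  stopifnot(C > 0, gamma > 0, k >= 1L, depth >= 1L, nTrees >= 1L)
  structure(list(kind = kind, C = C, gamma = gamma, degree = as.integer(degree),
                 k = as.integer(k), depth = as.integer(depth),
                 nTrees = as.integer(nTrees)),
            class = "classifierConfig")
}

# deterministic stratified fold assignment
.stratifiedFolds <- function(y, folds, seed) {
  y <- as.factor(y)
  if (any(table(y) < folds))
    stop("stratification error: every class needs at least ", folds,
         " members for ", folds, "-fold CV")
  fold <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

.standardizeFit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
.standardizeApply <- function(X, sc) sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")

# kNN with per-class vote fractions and deterministic tie handling:
# ties in the vote are broken toward the class with the smaller mean
# neighbour distance, then class order.
.knnPredict <- function(trainX, trainY, testX, k) {
  lev <- levels(trainY)
  k <- min(k, nrow(trainX))
  d2 <- outer(rowSums(testX^2), rep(1, nrow(trainX))) +
        outer(rep(1, nrow(testX)), rowSums(trainX^2)) -
        2 * testX %*% t(trainX)
  prob <- matrix(0, nrow(testX), length(lev), dimnames = list(NULL, lev))
  pred <- character(nrow(testX))
  for (i in seq_len(nrow(testX))) {
    o <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    votes <- table(factor(trainY[o], levels = lev))
    prob[i, ] <- as.numeric(votes) / k
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      md <- vapply(top, function(cl)
        mean(d2[i, o[trainY[o] == cl]]), numeric(1))
      top <- top[order(md, match(top, lev))][1L]
    }
    pred[i] <- top
  }
  list(pred = factor(pred, levels = lev), prob = prob)
}

# fit on the training split, return predictions + per-class scores on test
.fitPredict <- function(trainX, trainY, testX, config, seed,
                        wantProb = TRUE) {
  lev <- levels(trainY)
  kind <- config$kind
  if (kind %in% c("svm_poly", "svm_rbf", "knn")) {
    sc <- .standardizeFit(trainX)
    trainX <- .standardizeApply(trainX, sc)
    testX <- .standardizeApply(testX, sc)
  }
  if (kind == "knn")
    return(.knnPredict(trainX, trainY, testX, config$k))
  if (kind == "rf") {
    set.seed(seed)
    fit <- randomForest::randomForest(
      x = trainX, y = trainY, ntree = config$nTrees,
      maxnodes = min(2L^config$depth, nrow(trainX)))
    prob <- predict(fit, testX, type = "prob")[, lev, drop = FALSE]
    pred <- factor(lev[max.col(prob, ties.method = "first")], levels = lev)
    return(list(pred = pred, prob = prob))
  }
  # SVM: one-vs-one pairwise voting is e1071's native multi-class scheme
  set.seed(seed)
  fit <- e1071::svm(
    x = trainX, y = trainY, scale = FALSE, cost = config$C,
    kernel = if (kind == "svm_poly") "polynomial" else "radial",
    degree = config$degree, coef0 = 0,
    gamma = if (kind == "svm_poly") 1 else config$gamma,
    probability = wantProb)
  pr <- predict(fit, testX, probability = wantProb)
  prob <- if (wantProb)
    attr(pr, "probabilities")[, lev, drop = FALSE]
  else NULL
  list(pred = factor(as.character(pr), levels = lev), prob = prob)
}

.metricsFromConfusion <- function(conf) {
  n <- sum(conf)
  w <- rowSums(conf) / n
  sens <- spec <- numeric(nrow(conf))
  for (c in seq_len(nrow(conf))) {
    TP <- conf[c, c]; FN <- sum(conf[c, ]) - TP
    FP <- sum(conf[, c]) - TP; TN <- n - TP - FN - FP
    sens[c] <- if (TP + FN > 0) TP / (TP + FN) else 0
    spec[c] <- if (TN + FP > 0) TN / (TN + FP) else 0
  }
  list(accuracy = sum(diag(conf)) / n,
       sensitivity = sum(w * sens), specificity = sum(w * spec))
}

#' Stratified k-fold cross-validated evaluation
#'
#' Evaluates one classifier configuration with stratified tenfold
#' cross-validation: per-fold feature standardization (SVM/kNN), pooled
#' out-of-fold confusion matrix, and the derived metrics.  Sensitivity and
#' specificity are class-frequency-weighted one-vs-rest rates; AUC is the
#' weighted one-vs-rest area under the ROC of the out-of-fold class scores.
#'
#' @param features numeric matrix or data.frame of predictors (rows =
#'   images).
#' @param labels factor or character vector of class labels.
#' @param config a \code{\link{classifierConfig}}.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed controlling fold assignment and stochastic
#'   fits; identical seed, data and config give an identical report.
#' @return an \code{\linkS4class{EvalReport}}.
#' @export
evaluateCV <- function(features, labels, config = classifierConfig(),
                       folds = 10L, seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2L) stop("need at least two classes")
  folds <- as.integer(folds)
  fold <- .stratifiedFolds(y, folds, seed)
  lev <- levels(y)
  prob <- matrix(NA_real_, nrow(X), length(lev),
                 dimnames = list(NULL, lev))
  pred <- factor(rep(lev[1L], nrow(X)), levels = lev)
  for (f in seq_len(folds)) {
    te <- fold == f
    fit <- .fitPredict(X[!te, , drop = FALSE], droplevels(y[!te]),
                       X[te, , drop = FALSE], config,
                       seed = seed * 1000L + f)
    pred[te] <- as.character(fit$pred)
    if (!is.null(fit$prob)) prob[te, colnames(fit$prob)] <- fit$prob
  }
  conf <- table(truth = y, predicted = pred)
  conf <- matrix(as.integer(conf), nrow = nrow(conf),
                 dimnames = dimnames(conf))
  m <- .metricsFromConfusion(conf)
  w <- as.numeric(table(y)) / length(y)
  aucs <- vapply(seq_along(lev), function(ci) {
    sc <- prob[, ci]
    if (anyNA(sc)) return(NA_real_)
    as.numeric(pROC::auc(response = factor(y == lev[ci],
                                           levels = c(FALSE, TRUE)),
                         predictor = sc, direction = "<", quiet = TRUE))
  }, numeric(1))
  aucW <- if (anyNA(aucs)) NA_real_ else sum(w * aucs)
  new("EvalReport", confusion = conf, accuracy = m$accuracy,
      sensitivity = m$sensitivity, specificity = m$specificity,
      auc = if (is.na(aucW)) 0 else aucW,
      bestParams = unclass(config), folds = folds,
      seed = as.integer(seed))
}

# candidate grids, ordered by increasing model complexity so that the
# first maximum realizes the smaller-complexity tie-break
.parameterGrid <- function(kind) {
  tenSteps <- 10^(-2:3)
  switch(kind,
    svm_poly = lapply(tenSteps, function(C) list(C = C)),
    svm_rbf = {
      g <- expand.grid(C = tenSteps, gamma = tenSteps)
      g <- g[order(g$C, g$gamma), ]
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    knn = lapply(1:10, function(k) list(k = k)),
    rf = {
      g <- expand.grid(depth = 1:10, nTrees = seq(10L, 100L, by = 5L))
      g <- g[order(g$depth, g$nTrees), ]
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    stop("unknown classifier kind: ", kind))
}

#' Grid search with tenfold cross-validation
#'
#' Exhaustive search over the reference hyperparameter grids (C and gamma
#' from 0.01 to 1000 in decade steps, k from 1 to 10, tree depth 1 to 10
#' with 10 to 100 trees in steps of 5), selecting the configuration with
#' the highest cross-validated accuracy.  Ties are broken toward the
#' less complex model (smaller C/gamma, k, depth).
#'
#' @inheritParams evaluateCV
#' @param kind classifier kind, see \code{\link{classifierConfig}}.
#' @return the winning \code{\link{classifierConfig}}, with attributes
#'   \code{cvAccuracy} (best mean CV accuracy) and \code{nEvaluated}.
#' @export
gridSearchCV <- function(features, labels,
                         kind = c("svm_poly", "svm_rbf", "knn", "rf"),
                         folds = 10L, seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- droplevels(as.factor(labels))
  folds <- as.integer(folds)
  fold <- .stratifiedFolds(y, folds, seed)
  grid <- .parameterGrid(kind)
  if (!length(grid)) stop("empty parameter grid")
  best <- NULL; bestAcc <- -Inf
  for (params in grid) {
    config <- do.call(classifierConfig, c(list(kind = kind), params))
    hit <- 0L
    for (f in seq_len(folds)) {
      te <- fold == f
      fit <- .fitPredict(X[!te, , drop = FALSE], droplevels(y[!te]),
                         X[te, , drop = FALSE], config,
                         seed = seed * 1000L + f, wantProb = FALSE)
      hit <- hit + sum(fit$pred == y[te])
    }
    acc <- hit / length(y)
    if (acc > bestAcc) {        # strict: ties keep the simpler model
      bestAcc <- acc
      best <- config
    }
  }
  attr(best, "cvAccuracy") <- bestAcc
  attr(best, "nEvaluated") <- length(grid)
  best
}
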