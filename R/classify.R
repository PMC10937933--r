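## Imbalance-aware classification of crosslinking status.
##
## Random forests (ranger) are the primary model; logistic regression, SVM,
## gradient-boosted trees and a seed-averaged neural network are evaluated
## under the identical resampling protocol. SMOTE is applied inside each
## training fold only, never to held-out data.

#' Cross-validation configuration
#' @param k Folds (default 10), stratified by label.
#' @param seed RNG seed for fold assignment.
#' @return Named list.
#' @export
cvConfig <- function(k = 10, seed = 1) list(k = k, seed = seed)

#' SMOTE configuration
#' @param kNeighbors Nearest minority neighbors (default 5).
#' @param ratio Target minority/majority ratio (default 1, i.e. 1:1).
#' @param seed RNG seed for interpolation.
#' @param insideFolds Apply SMOTE inside each training fold (default TRUE;
#'   FALSE reproduces the leaky outside-fold variant for comparison).
#' @param enabled Set FALSE to disable oversampling entirely.
#' @return Named list.
#' @export
smoteConfig <- function(kNeighbors = 5, ratio = 1, seed = 1,
                        insideFolds = TRUE, enabled = TRUE)
  list(kNeighbors = kNeighbors, ratio = ratio, seed = seed,
       insideFolds = insideFolds, enabled = enabled)

#' Random-forest hyperparameters
#'
#' Defaults per task: nucleotides mtry 17 / ntree 100; amino acids mtry 6 /
#' ntree 1000; ribosome mtry 6 / ntree 100.
#'
#' @param task One of \code{"nucleotide"}, \code{"amino-acid"},
#'   \code{"ribosome"}, or \code{NULL} to give mtry/ntree directly.
#' @param mtry Features tried per split.
#' @param ntree Trees per forest.
#' @return Named list with \code{mtry} and \code{ntree}.
#' @export
rfConfig <- function(task = NULL, mtry = NULL, ntree = NULL) {
  if (!is.null(task)) {
    task <- match.arg(task, c("nucleotide", "amino-acid", "ribosome"))
    def <- switch(task,
                  "nucleotide" = list(mtry = 17, ntree = 100),
                  "amino-acid" = list(mtry = 6, ntree = 1000),
                  "ribosome" = list(mtry = 6, ntree = 100))
    if (is.null(mtry)) mtry <- def$mtry
    if (is.null(ntree)) ntree <- def$ntree
  }
  stopifnot(!is.null(mtry), !is.null(ntree))
  list(mtry = mtry, ntree = ntree)
}

## Stratified fold assignment; every fold gets >= 1 positive or an error.
#' @keywords internal
.stratifiedFolds <- function(y, k, seed) {
  fold <- integer(length(y))
  .withSeed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(tapply(y == 1, fold, sum) == 0))
    stop("a fold has no positives; reduce k or reseed")
  fold
}

## Model fitting/scoring backends. Each fit function returns an object the
## matching score function turns into P(class 1).
#' @keywords internal
.fitModel <- function(method, x, y, params, seed) {
  x <- as.matrix(x)
  switch(method,
    rf = .withSeed(seed, ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)),
      num.trees = params$ntree,
      mtry = min(params$mtry, ncol(x)),
      probability = TRUE, seed = seed, num.threads = 1)),
    logistic = {
      df <- data.frame(y = y, x)
      suppressWarnings(stats::glm(y ~ ., data = df,
                                  family = stats::binomial()))
    },
    svm = .withSeed(seed, e1071::svm(
      x, factor(y, levels = c(0, 1)), probability = TRUE,
      kernel = "radial", scale = apply(x, 2, stats::sd) > 0)),
    xgboost = .withSeed(seed, xgboost::xgboost(
      x = x, y = factor(y, levels = c(0, 1)), nrounds = 50, max_depth = 3,
      learning_rate = 0.3, nthread = 1, verbosity = 0)),
    avnnet = {
      nets <- lapply(seq_len(5), function(s) .withSeed(seed + s, {
        sc <- apply(x, 2, stats::sd)
        xs <- scale(x, scale = ifelse(sc > 0, sc, 1))
        fit <- nnet::nnet(xs, y, size = 5, decay = 0.1, maxit = 200,
                          trace = FALSE, entropy = TRUE,
                          MaxNWts = 50000)
        list(fit = fit, center = attr(xs, "scaled:center"),
             scale = attr(xs, "scaled:scale"))
      }))
      structure(nets, class = "avnnet")
    },
    stop("unknown model method: ", method))
}

#' @keywords internal
.scoreModel <- function(method, fit, x) {
  x <- as.matrix(x)
  switch(method,
    rf = stats::predict(fit, data = x, num.threads = 1)$predictions[, "1"],
    logistic = as.numeric(stats::predict(
      fit, newdata = as.data.frame(x), type = "response")),
    svm = {
      pr <- stats::predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    xgboost = as.numeric(stats::predict(fit, x, type = "response")),
    avnnet = {
      scores <- vapply(fit, function(m) {
        xs <- scale(x, center = m$center, scale = m$scale)
        as.numeric(stats::predict(m$fit, xs))
      }, numeric(nrow(x)))
      rowMeans(as.matrix(scores))
    })
}

#' @keywords internal
.aucOf <- function(y, score) {
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c("0", "1"), direction = "<",
                                 quiet = TRUE)))
}

#' Cross-validated ROC AUC with SMOTE and bootstrap confidence interval
#'
#' Evaluates a classifier by stratified k-fold cross-validation: SMOTE is
#' applied to each training fold only, the held-out predictions are pooled
#' and a single ROC AUC is computed. The 95 percent confidence interval
#' comes from \code{bootstrap} refits on row-resampled data scored on their
#' out-of-bag rows (percentiles 2.5 / 97.5).
#'
#' @param x Feature matrix (rows = labeled sites).
#' @param y Binary labels (0/1); both classes must be present.
#' @param method One of \code{"rf"}, \code{"logistic"}, \code{"svm"},
#'   \code{"xgboost"}, \code{"avnnet"}.
#' @param cv \code{cvConfig()}.
#' @param smote \code{smoteConfig()}.
#' @param params Model hyperparameters (\code{rfConfig()} for rf).
#' @param bootstrap Number of bootstrap models for the CI (0 disables;
#'   default 0 — pass 2000 for the full protocol).
#' @return List: \code{auc}, \code{ciLower}, \code{ciUpper},
#'   \code{foldScores} (per-fold AUC), \code{predictions} (pooled held-out
#'   scores in row order), \code{folds}.
#' @export
crossvalAUC <- function(x, y, method = "rf", cv = cvConfig(),
                        smote = smoteConfig(), params = rfConfig("nucleotide"),
                        bootstrap = 0) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(length(unique(y)) == 2)
  if (!smote$insideFolds && smote$enabled) {
    ## leaky variant, for comparison only
    aug <- smoteBalance(x, y, ratio = smote$ratio, k = smote$kNeighbors,
                        seed = smote$seed)
    x <- aug$x; y <- aug$y
  }
  fold <- .stratifiedFolds(y, cv$k, cv$seed)
  score <- rep(NA_real_, length(y))
  foldScores <- numeric(cv$k)
  for (f in seq_len(cv$k)) {
    tr <- fold != f
    xt <- x[tr, , drop = FALSE]; yt <- y[tr]
    if (smote$enabled && smote$insideFolds) {
      aug <- smoteBalance(xt, yt, ratio = smote$ratio,
                          k = smote$kNeighbors, seed = smote$seed + f)
      xt <- aug$x; yt <- aug$y
    }
    fit <- .fitModel(method, xt, yt, params, seed = cv$seed * 1000 + f)
    score[!tr] <- .scoreModel(method, fit, x[!tr, , drop = FALSE])
    foldScores[f] <- if (length(unique(y[!tr])) == 2)
      .aucOf(y[!tr], score[!tr]) else NA_real_
  }
  auc <- .aucOf(y, score)
  ciLower <- ciUpper <- NA_real_
  if (bootstrap > 0) {
    boots <- .withSeed(cv$seed + 7777, {
      vapply(seq_len(bootstrap), function(b) {
        idx <- sample.int(length(y), replace = TRUE)
        oob <- setdiff(seq_along(y), unique(idx))
        if (length(unique(y[oob])) < 2) return(NA_real_)
        xt <- x[idx, , drop = FALSE]; yt <- y[idx]
        if (smote$enabled) {
          aug <- smoteBalance(xt, yt, ratio = smote$ratio,
                              k = smote$kNeighbors, seed = smote$seed + b)
          xt <- aug$x; yt <- aug$y
        }
        fit <- .fitModel(method, xt, yt, params, seed = cv$seed * 100 + b)
        .aucOf(y[oob], .scoreModel(method, fit, x[oob, , drop = FALSE]))
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
    ciLower <- unname(qs[1]); ciUpper <- unname(qs[2])
  }
  list(auc = auc, ciLower = ciLower, ciUpper = ciUpper,
       foldScores = foldScores, predictions = score, folds = fold)
}

#' Compare alternative classifiers under one resampling protocol
#'
#' Evaluates logistic regression, SVM, gradient-boosted trees and the
#' seed-averaged neural network (plus the random forest) with identical
#' folds and SMOTE settings.
#'
#' @inheritParams crossvalAUC
#' @param methods Model families to run.
#' @return data.frame with columns \code{method} and \code{auc}.
#' @export
altClassifiers <- function(x, y, cv = cvConfig(), smote = smoteConfig(),
                           params = rfConfig("nucleotide"),
                           methods = c("rf", "logistic", "svm", "xgboost",
                                       "avnnet")) {
  aucs <- vapply(methods, function(m) {
    res <- tryCatch(crossvalAUC(x, y, method = m, cv = cv, smote = smote,
                                params = params),
                    error = function(e) {
                      warning("model ", m, " failed: ",
                              conditionMessage(e))
                      list(auc = NA_real_)
                    })
    res$auc
  }, numeric(1))
  data.frame(method = methods, auc = unname(aucs),
             stringsAsFactors = FALSE)
}
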