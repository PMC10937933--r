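## Feature-importance ranking: Gini importance, permutation robustness and
## elastic-net direction signs.

#' Mean Gini decrease of a random forest
#'
#' Trains a (optionally SMOTE-balanced) random forest on the full dataset
#' and returns the impurity-based importance: the total Gini impurity
#' decrease attributable to splits on each feature, averaged over trees.
#'
#' @param x Feature matrix.
#' @param y Binary labels (0/1).
#' @param params \code{rfConfig()}.
#' @param smote \code{smoteConfig()}; disabled by default for ranking.
#'   SMOTE corrects the classifier's sensitivity under imbalance, but the
#'   interpolated synthetic rows perturb impurity-based rankings, so
#'   importance is ranked on the original rows unless oversampling is
#'   explicitly requested.
#' @param seed RNG seed.
#' @return Named non-negative numeric vector, one entry per feature.
#' @export
giniImportance <- function(x, y, params = rfConfig("nucleotide"),
                           smote = smoteConfig(enabled = FALSE),
                           seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (smote$enabled) {
    aug <- smoteBalance(x, y, ratio = smote$ratio, k = smote$kNeighbors,
                        seed = smote$seed)
    x <- aug$x; y <- aug$y
  }
  fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        num.trees = params$ntree,
                        mtry = min(params$mtry, ncol(x)),
                        importance = "impurity", probability = FALSE,
                        seed = seed, num.threads = 1)
  fit$variable.importance
}

#' Permutation robustness of feature-importance ranks
#'
#' Measures how robust each feature's importance rank is against models
#' trained on label-permuted data. With true-model rank r_s (rank 1 = most
#' important, ties by average rank) and r_is the rank in the i-th of N
#' label permutations, the robustness is
#' R_s = -log10((sum_i I(r_is < r_s) + 1) / (N + 1)).
#'
#' The +1 pseudocount departs from the plain fraction only when no
#' permutation beats the true rank, where the bare -log10(0) is undefined;
#' it caps R_s at log10(N + 1).
#'
#' @inheritParams giniImportance
#' @param N Number of label permutations (2000 for the full protocol;
#'   smaller values for quick runs).
#' @return data.frame: \code{feature}, \code{meanGiniDecrease},
#'   \code{trueRank}, \code{nBetter}, \code{Rs}.
#' @export
permutationRobustness <- function(x, y, params = rfConfig("nucleotide"),
                                  smote = smoteConfig(enabled = FALSE),
                                  N = 2000, seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  imp <- giniImportance(x, y, params = params, smote = smote, seed = seed)
  trueRank <- rank(-imp, ties.method = "average")
  nBetter <- integer(length(imp))
  perms <- .withSeed(seed + 31L, {
    lapply(seq_len(N), function(i) sample(y))
  })
  for (i in seq_len(N)) {
    impI <- giniImportance(x, perms[[i]], params = params, smote = smote,
                           seed = seed + i)
    rI <- rank(-impI, ties.method = "average")
    nBetter <- nBetter + (rI < trueRank)
  }
  data.frame(feature = names(imp),
             meanGiniDecrease = unname(imp),
             trueRank = unname(trueRank),
             nBetter = nBetter,
             Rs = robustnessScore(nBetter, N),
             stringsAsFactors = FALSE)
}

#' Robustness score from a better-rank count
#'
#' @param nBetter Number of permutations in which the feature ranked better
#'   than in the true model.
#' @param N Number of permutations.
#' @return R_s values in [0, log10(N + 1)].
#' @export
robustnessScore <- function(nBetter, N) -log10((nBetter + 1) / (N + 1))

#' Elastic-net direction sign of each feature
#'
#' Fits an elastic-net-penalized logistic regression on standardized
#' features and attaches the sign of each coefficient as the direction of
#' its contribution to crosslinking. Zero coefficients give an undetermined
#' direction (NA). With \code{tune = TRUE} the mixing and penalty are
#' selected by 10-fold cross-validation maximizing AUC over a grid;
#' otherwise the supplied values are used (defaults: the nucleotide-task
#' optimum alpha 0.56, lambda 0.14).
#'
#' @param x Feature matrix.
#' @param y Binary labels (0/1).
#' @param alpha Elastic-net mixing in [0, 1].
#' @param lambda Penalty.
#' @param tune Tune (alpha, lambda) by CV instead of using the arguments.
#' @param seed RNG seed for CV folds when tuning.
#' @return data.frame: \code{feature}, \code{coefficient}, \code{sign}
#'   ("+", "-" or NA); attributes \code{alpha}, \code{lambda}.
#' @export
signedImportance <- function(x, y, alpha = 0.56, lambda = 0.14,
                             tune = FALSE, seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  sds <- apply(x, 2, stats::sd)
  xs <- scale(x, scale = ifelse(sds > 0, sds, 1))
  if (tune) {
    grid <- expand.grid(alpha = seq(0, 1, by = 0.1),
                        lambda = NA)
    best <- list(auc = -Inf)
    for (a in grid$alpha) {
      cvfit <- .withSeed(seed, glmnet::cv.glmnet(
        xs, y, family = "binomial", alpha = a, type.measure = "auc",
        nfolds = 10, standardize = FALSE))
      aucBest <- max(cvfit$cvm)
      if (aucBest > best$auc)
        best <- list(auc = aucBest, alpha = a,
                     lambda = cvfit$lambda[which.max(cvfit$cvm)])
    }
    alpha <- best$alpha
    lambda <- best$lambda
  }
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE)
  co <- as.numeric(stats::coef(fit))[-1]  # drop intercept
  out <- data.frame(feature = colnames(x),
                    coefficient = co,
                    sign = ifelse(co > 0, "+", ifelse(co < 0, "-", NA)),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "lambda") <- lambda
  out
}

#' Full importance report for a dataset
#'
#' Combines mean Gini decrease, permutation robustness and elastic-net
#' direction into one record per feature, ordered by importance.
#'
#' @inheritParams permutationRobustness
#' @param direction \code{signedImportance()} arguments as a list
#'   (\code{alpha}, \code{lambda}, \code{tune}).
#' @return data.frame: \code{feature}, \code{meanGiniDecrease},
#'   \code{trueRank}, \code{nBetter}, \code{Rs}, \code{coefficient},
#'   \code{sign}.
#' @export
importanceReport <- function(x, y, params = rfConfig("nucleotide"),
                             smote = smoteConfig(enabled = FALSE),
                             N = 2000, seed = 1,
                             direction = list(alpha = 0.56, lambda = 0.14,
                                              tune = FALSE)) {
  rob <- permutationRobustness(x, y, params = params, smote = smote,
                               N = N, seed = seed)
  sgn <- signedImportance(x, y, alpha = direction$alpha,
                          lambda = direction$lambda,
                          tune = isTRUE(direction$tune), seed = seed)
  out <- merge(rob, sgn, by = "feature", sort = FALSE)
  out <- out[order(out$trueRank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
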