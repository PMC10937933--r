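test_that("SMOTE interpolates on segments between minority neighbors", {
  ## exactly two minority points: every synthetic row is on their segment
  x <- rbind(c(0, 0), c(2, 4))
  syn <- smoteOversample(x, 50, k = 5, seed = 1) |> suppressWarnings()
  t <- syn[, 1] / 2
  expect_true(all(t >= 0 & t <= 1))
  expect_equal(syn[, 2], 4 * t, tolerance = 1e-12)
  ## coincident minority points collapse to that point
  xc <- rbind(c(1, 1), c(1, 1), c(1, 1))
  sync <- smoteOversample(xc, 10, k = 2, seed = 2)
  expect_true(all(sync == 1))
  expect_error(smoteOversample(rbind(c(0, 0)), 5), "at least 2")
})

test_that("SMOTE synthetic points lie inside the minority convex hull", {
  set.seed(7)
  x <- cbind(rnorm(20), rnorm(20))
  syn <- smoteOversample(x, 200, k = 5, seed = 3)
  expect_true(all(oracleInHull(x, syn)))
})

test_that("SMOTE augments without touching the original rows", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c(0, 1), c(15, 5))
  aug <- smoteBalance(x, y, seed = 4)
  expect_equal(aug$x[1:20, ], x, ignore_attr = TRUE)
  expect_equal(aug$y[1:20], y)
  expect_equal(sum(aug$y == 1), sum(aug$y == 0))
})

test_that("cross-validated AUC hits the expected extremes", {
  set.seed(11)
  ## perfectly separating single feature
  xs <- matrix(c(rnorm(60, 0), rnorm(60, 10)), ncol = 1,
               dimnames = list(NULL, "f1"))
  ys <- rep(c(0, 1), each = 60)
  expect_equal(crossvalAUC(xs, ys, cv = cvConfig(seed = 1))$auc, 1.0)
  ## labels independent of features
  nullSim <- simulateFeatureTable(nPos = 100, nNeg = 300, nFeatures = 20,
                                  informative = integer(0), seed = 21)
  aucNull <- crossvalAUC(nullSim$x, nullSim$y, cv = cvConfig(seed = 2))$auc
  expect_gt(aucNull, 0.4)
  expect_lt(aucNull, 0.6)
})

test_that("AUC approaches the Bayes oracle on strongly informative tables", {
  sim <- simulateFeatureTable(nPos = 200, nNeg = 600, nFeatures = 8,
                              informative = 1:5, beta = 2.5, seed = 5)
  got <- crossvalAUC(sim$x, sim$y, cv = cvConfig(seed = 3))$auc
  bayes <- as.numeric(pROC::auc(pROC::roc(
    sim$y, sim$logOdds, levels = c("0", "1"), direction = "<",
    quiet = TRUE)))
  expect_lt(abs(got - bayes), 0.05)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  y <- rbinom(100, 1, 0.3)
  score <- rnorm(100) + y
  a1 <- pROC::auc(pROC::roc(y, score, levels = c("0", "1"),
                            direction = "<", quiet = TRUE))
  a2 <- pROC::auc(pROC::roc(y, exp(3 * score), levels = c("0", "1"),
                            direction = "<", quiet = TRUE))
  expect_equal(as.numeric(a1), as.numeric(a2))
})

test_that("bootstrap CI brackets the cross-validated AUC", {
  sim <- simulateFeatureTable(nPos = 60, nNeg = 140, nFeatures = 10,
                              informative = 1:3, beta = 2, seed = 8)
  res <- crossvalAUC(sim$x, sim$y, cv = cvConfig(seed = 4), bootstrap = 40)
  expect_lte(res$ciLower, res$auc + 0.05)
  expect_gte(res$ciUpper, res$auc - 0.05)
  expect_lt(res$ciLower, res$ciUpper)
})

test_that("Gini importance matches the hand stump computation and rF oracle", {
  ## 4 rows, single perfectly splitting feature, one stump: root Gini 0.5,
  ## children pure; node-size-weighted decrease = 4 x 0.5 = 2
  x <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "f1"))
  y <- c(0, 0, 1, 1)
  fit <- ranger::ranger(x = x, y = factor(y), num.trees = 1, mtry = 1,
                        importance = "impurity", seed = 1, num.threads = 1,
                        replace = FALSE, sample.fraction = 1)
  expect_equal(unname(fit$variable.importance), 4 * 0.5)
  rf <- randomForest::randomForest(x = x, y = factor(y), ntree = 1,
                                   mtry = 1, replace = FALSE, sampsize = 4)
  expect_equal(unname(fit$variable.importance),
               unname(randomForest::importance(rf)[, 1]))
})

test_that("noise features rank far below informative ones", {
  set.seed(5)
  x <- cbind(info = rep(c(0, 1), each = 50), noise = rnorm(100))
  y <- rep(c(0, 1), each = 50)
  imp <- giniImportance(x, y, params = rfConfig(mtry = 2, ntree = 100),
                        seed = 2)
  expect_lt(imp["noise"], 0.1 * imp["info"])
  ## column permutation leaves per-feature importances attached correctly
  imp2 <- giniImportance(x[, c("noise", "info")], y,
                         params = rfConfig(mtry = 2, ntree = 100), seed = 2)
  expect_gt(imp2["info"], imp2["noise"])
  expect_equal(unname(imp2["info"]), unname(imp["info"]),
               tolerance = 0.25)
})

test_that("robustness arithmetic follows the pseudocount rule", {
  expect_equal(robustnessScore(0, 2000), log10(2001))
  expect_equal(robustnessScore(3, 2000), -log10(4 / 2001))
  expect_equal(robustnessScore(2000, 2000), 0)
  ## antitone in the number of better-ranked permutations, bounded
  rs <- robustnessScore(0:2000, 2000)
  expect_true(all(diff(rs) < 0))
  expect_true(all(rs >= 0 & rs <= log10(2001)))
})

test_that("permutation robustness separates signal from null features", {
  ## informative features drawn at the null rate, so only the label signal
  ## (not a variance artifact) can lift their ranks
  sim <- simulateFeatureTable(nPos = 60, nNeg = 180, nFeatures = 30,
                              informative = 1:3, beta = 2.5,
                              informativeRate = 0.3, seed = 13)
  rob <- permutationRobustness(sim$x, sim$y,
                               params = rfConfig(mtry = 10, ntree = 200),
                               N = 100, seed = 2)
  expect_true(all(rob$Rs >= 0 & rob$Rs <= log10(101)))
  expect_gt(min(rob$Rs[sim$informative]),
            stats::median(rob$Rs[-sim$informative]))
  ## R_s consistent with the recorded better-rank counts
  expect_equal(rob$Rs, -log10((rob$nBetter + 1) / 101))
})

test_that("elastic-net signs recover the generative directions", {
  set.seed(17)
  n <- 300
  x <- cbind(up = rnorm(n), down = rnorm(n), null = rnorm(n))
  lo <- 1.5 * x[, "up"] - 1.5 * x[, "down"]
  y <- rbinom(n, 1, plogis(lo))
  sgn <- signedImportance(x, y, alpha = 0.5, lambda = 0.05)
  expect_identical(sgn$sign[sgn$feature == "up"], "+")
  expect_identical(sgn$sign[sgn$feature == "down"], "-")
  ## agreement with an unpenalized IRLS (glm) oracle at weak penalty
  oracle <- sign(coef(glm(y ~ x, family = binomial()))[-1])
  weak <- signedImportance(x, y, alpha = 0, lambda = 1e-4)
  expect_equal(ifelse(weak$sign == "+", 1, -1), unname(oracle),
               ignore_attr = TRUE)
})

test_that("alternative classifiers behave together under one protocol", {
  set.seed(2)
  xs <- matrix(c(rnorm(50, 0), rnorm(50, 8)), ncol = 1,
               dimnames = list(NULL, "f1"))
  ys <- rep(c(0, 1), each = 50)
  sep <- altClassifiers(xs, ys, cv = cvConfig(k = 5, seed = 1))
  expect_true(all(sep$auc >= 0.99))
  expect_equal(sep$auc[sep$method == "rf"], 1.0)
  ## on an informative table all methods land in a narrow band
  sim <- simulateFeatureTable(nPos = 80, nNeg = 240, nFeatures = 10,
                              informative = 1:5, beta = 2, seed = 6)
  res <- altClassifiers(sim$x, sim$y, cv = cvConfig(seed = 2),
                        params = rfConfig(mtry = 3, ntree = 100))
  expect_lte(diff(range(res$auc)), 0.1)
})

test_that("the classification pipeline is reproducible under a fixed seed", {
  sim <- simulateFeatureTable(nPos = 40, nNeg = 120, nFeatures = 15,
                              informative = 1:3, beta = 2, seed = 3)
  r1 <- crossvalAUC(sim$x, sim$y, cv = cvConfig(seed = 9))
  r2 <- crossvalAUC(sim$x, sim$y, cv = cvConfig(seed = 9))
  expect_identical(r1$predictions, r2$predictions)
  i1 <- permutationRobustness(sim$x, sim$y,
                              params = rfConfig(mtry = 4, ntree = 50),
                              N = 20, seed = 5)
  i2 <- permutationRobustness(sim$x, sim$y,
                              params = rfConfig(mtry = 4, ntree = 50),
                              N = 20, seed = 5)
  expect_identical(i1, i2)
})
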