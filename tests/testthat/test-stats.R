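test_that("composition test gives p = 1 on identical compositions", {
  tab <- rbind(c(30, 20, 10), c(30, 20, 10))
  res <- compositionTest(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("composition test statistic matches hand arithmetic on 2x2", {
  res <- compositionTest(rbind(c(10, 0), c(0, 10)))
  expect_equal(res$statistic, 20)
})

test_that("chi-squared p agrees with a Monte-Carlo permutation oracle", {
  ## counts large enough for the asymptotic and permutation references to
  ## coincide within simulation error
  ## the margin-conditioned Monte-Carlo reference and the asymptotic
  ## Pearson p agree to a few percent once expected counts are large
  set.seed(12)
  for (rep in 1:3) {
    tab <- matrix(rpois(4, 500) + 100, 2)
    p <- compositionTest(tab)$p
    mc <- stats::chisq.test(tab, correct = FALSE,
                            simulate.p.value = TRUE, B = 20000)$p.value
    expect_lt(abs(p - mc), 0.04)
  }
})

test_that("Fisher's exact test matches printed small-table values", {
  res <- fisherExact(rbind(c(2, 1), c(1, 2)))
  expect_equal(res$oddsRatio, 4)
  expect_equal(fisherExact(rbind(c(5, 5), c(5, 5)))$p, 1)
  ## the Cys vs Phe+Tyr contacting-proportion table
  res2 <- fisherExact(rbind(c(4, 12), c(34, 6)))
  oracle <- stats::fisher.test(rbind(c(4, 12), c(34, 6)))$p.value
  expect_equal(res2$p, oracle, tolerance = 1e-9)
})

test_that("Fisher p equals full hypergeometric enumeration for all margins <= 12", {
  for (r1 in 1:12) for (r2 in 1:12) {
    k <- max(1, r1 %/% 2)
    for (a in max(0, k - r2):min(k, r1)) {
      tab <- rbind(c(a, r1 - a), c(k - a, r2 - (k - a)))
      if (any(colSums(tab) == 0)) next
      p <- fisherExact(tab)$p
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("Fisher p is symmetric under simultaneous row and column swaps", {
  set.seed(3)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(fisherExact(tab)$p, fisherExact(tab[2:1, 2:1])$p,
                 tolerance = 1e-12)
  }
})

test_that("binomial rate comparison uses the group-b null", {
  expect_gte(rateComparison(5, 50, 10, 100)$p, 0.5)   # equal rates
  expect_equal(rateComparison(0, 30, 0, 40)$p, 1)     # no events anywhere
  ## toy counts against a manual tail-sum oracle
  res <- rateComparison(12, 40, 6, 60)
  p0 <- 6 / 60
  dens <- dbinom(0:40, 40, p0)
  pOracle <- sum(dens[dens <= dens[13] * (1 + 1e-7)])
  expect_equal(res$p, pOracle, tolerance = 1e-9)
})

test_that("crosslink projection maps sites through alignment gaps", {
  aln <- c(p1 = "MKFLG", p2 = "MKFLG", p3 = "MKFLG")
  sites <- data.frame(protein = "p2", position = 3, aa = "F")
  pr <- projectCrosslinks(aln, sites)
  expect_equal(pr$mapped$column, 3)
  ## a gap before the site shifts it one column right
  aln2 <- c(p1 = "MKFLG-", p2 = "MK-FLG")
  pr2 <- projectCrosslinks(aln2, data.frame(protein = "p2", position = 3,
                                            aa = "F"))
  expect_equal(pr2$mapped$column, 4)
  ## mismatching site letter errors with context
  expect_error(projectCrosslinks(aln, data.frame(protein = "p1",
                                                 position = 3, aa = "W")),
               "mismatch")
})

test_that("information content is closed-form for pure columns", {
  aln <- c(a = "FFF", b = "FFF", c = "FFF")
  pr <- projectCrosslinks(aln, data.frame(protein = "a", position = 1,
                                          aa = "F"))
  expect_equal(pr$profile$ic, rep(log2(20), 3), tolerance = 1e-12)
  ## uniform 20-residue column has zero information
  aln20 <- setNames(strsplit(paste(xlink3d:::.AA_LETTERS, collapse = ""),
                             "")[[1]],
                    paste0("s", 1:20))
  pr20 <- projectCrosslinks(aln20, data.frame(protein = "s1", position = 1,
                                              aa = "A"))
  expect_equal(pr20$profile$ic[1], 0, tolerance = 1e-12)
})

test_that("projection conserves crosslink counts and ignores sequence order", {
  aln <- c(p1 = "MKFLG", p2 = "MKFLG", p3 = "MKFLG")
  sites <- data.frame(protein = c("p1", "p2", "p3"),
                      position = c(1, 3, 3), aa = c("M", "F", "F"))
  pr <- projectCrosslinks(aln, sites)
  expect_equal(sum(pr$profile$crosslinks), nrow(sites))
  prRev <- projectCrosslinks(rev(aln), sites)
  expect_equal(prRev$profile$ic, pr$profile$ic)
})
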