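test_that("crosslink frequencies match direct arithmetic", {
  ## 10 instances, all crosslinked at offset 2
  fr <- positionCrosslinkFrequency(replicate(10, 2L, simplify = FALSE), 5)
  expect_equal(fr$frequency[fr$position == 2], 1.0)
  expect_equal(attr(fr, "nInstances"), 10)
  ## 25 instances with crosslinks, 10 at offset 3
  offs <- c(replicate(10, 3L, simplify = FALSE),
            replicate(15, 0L, simplify = FALSE))
  fr2 <- positionCrosslinkFrequency(offs, 6)
  expect_equal(fr2$frequency[fr2$position == 3], 0.4)
  ## counts conserved
  expect_equal(sum(fr2$count), 25)
})

test_that("frequencies equal a brute-force per-row tally on random tables", {
  set.seed(9)
  for (rep in 1:5) {
    L <- sample(4:9, 1)
    offs <- lapply(1:30, function(i) {
      k <- sample(0:3, 1)
      if (k == 0) integer(0) else sample(0:(L - 1), k)
    })
    fr <- positionCrosslinkFrequency(offs, L)
    withXL <- sum(vapply(offs, function(o) length(o) > 0, logical(1)))
    manual <- vapply(0:(L - 1), function(p)
      sum(vapply(offs, function(o) p %in% o, logical(1))), numeric(1))
    expect_equal(fr$count, as.integer(manual))
    expect_equal(fr$frequency, manual / withXL)
  }
})

test_that("frequency errors on empty or out-of-range input", {
  expect_error(positionCrosslinkFrequency(list(), 5), "empty")
  expect_error(positionCrosslinkFrequency(list(5L), 5), "instance 1")
  expect_error(positionCrosslinkFrequency(list(integer(0)), 5),
               "no instance carries")
})

test_that("the two-branch threshold rule labels positions correctly", {
  mk <- function(f) data.frame(position = 0L, count = 0L, frequency = f)
  call1 <- function(f, n) callCrosslinkedPositions(mk(f), n)$label
  expect_identical(call1(0.4, 25), "crosslinked")       # primary branch
  expect_identical(call1(0.42, 12), "non-crosslinked")  # fails both
  expect_identical(call1(0.58, 12), "crosslinked")      # fallback branch
  expect_identical(call1(0.29, 25), "non-crosslinked")
  expect_identical(call1(0.9, 9), "non-crosslinked")    # too few instances
  ## boundary inclusivity
  expect_identical(call1(0.3, 20), "crosslinked")
  expect_identical(call1(0.5, 10), "crosslinked")
})

test_that("crosslink calling is monotone in counts", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    f <- runif(1)
    lab <- callCrosslinkedPositions(
      data.frame(position = 0L, count = 0L, frequency = f), n)$label
    labUp <- callCrosslinkedPositions(
      data.frame(position = 0L, count = 0L,
                 frequency = min(1, f + runif(1, 0, 1 - f))),
      n + sample(0:20, 1))$label
    if (lab == "crosslinked") expect_identical(labUp, "crosslinked")
  }
})

test_that("protein sites map through truncation and survive mismatches", {
  s <- makeInterfaceFixture("UGCAUGUA", stackedAt = c(2, 4, 6, 8))
  ## identical numbering
  m <- mapProteinSiteToChain(s, "P", "FFFF", 3, "F")
  expect_true(m$mapped)
  expect_equal(m$resno, 3)
  ## full sequence with an N-terminal extension absent from the chain:
  ## positions shift consistently
  m2 <- mapProteinSiteToChain(s, "P", "MKLFFFF", 6, "F")
  expect_true(m2$mapped)
  expect_equal(m2$resno, 3)
  expect_equal(m2$resno,
               oracleAlignMap("MKLFFFF", "FFFF", 6))
  ## letter mismatch at the site is rejected
  bad <- mapProteinSiteToChain(s, "P", "FFFF", 3, "W")
  expect_false(bad$mapped)
})

test_that("mapping agrees with the Needleman-Wunsch oracle under a mismatch", {
  seqChain <- "FAFAFAFAFA"
  s <- makeInterfaceFixture(paste(rep("U", 10), collapse = ""),
                            stackedAt = 1:10)
  at <- atoms(s)
  aa3 <- c(F = "PHE", A = "ALA")
  letters <- strsplit(seqChain, "")[[1]]
  at$resid[at$chain == "P"] <- aa3[letters[at$resno[at$chain == "P"]]]
  s2 <- newComplexStructure(at[, c("chain", "resno", "insert", "resid",
                                   "elety", "elesy", "x", "y", "z", "o",
                                   "alt")])
  full <- "FAFGFAFAFA"   # one engineered mismatch at position 4
  m <- mapProteinSiteToChain(s2, "P", full, 7, "F")
  expect_true(m$mapped)
  expect_equal(m$resno, oracleAlignMap(full, seqChain, 7))
})

test_that("nonredundant selection maximizes lexicographically", {
  cand <- data.frame(accession = c("2ERR", "1ABC"),
                     crosslinkCount = c(5, 3), nonzeroFeatures = c(10, 50))
  expect_identical(selectNonredundant(cand), "2ERR")
  cand2 <- data.frame(accession = c("2ERR", "1ABC"),
                      crosslinkCount = c(5, 5), nonzeroFeatures = c(30, 40))
  expect_identical(selectNonredundant(cand2), "1ABC")
  cand3 <- data.frame(accession = c("9ZZZ", "1AAA"),
                      crosslinkCount = c(5, 5), nonzeroFeatures = c(40, 40))
  expect_identical(selectNonredundant(cand3), "1AAA")
  ## permutation invariance
  set.seed(2)
  cand4 <- data.frame(accession = sprintf("S%02d", 1:6),
                      crosslinkCount = sample(1:3, 6, TRUE),
                      nonzeroFeatures = sample(1:50, 6))
  picks <- vapply(1:10, function(i)
    selectNonredundant(cand4[sample(6), ]), character(1))
  expect_equal(length(unique(picks)), 1)
})

test_that("contact-split crosslinking frequencies match a recount oracle", {
  labels <- data.frame(
    key = sprintf("P:%d:.", 1:20),
    residue = c(rep("F", 10), rep("C", 6), rep("R", 4)),
    label = c(rep("crosslinked", 2), rep("non-crosslinked", 8),
              rep("crosslinked", 1), rep("non-crosslinked", 5),
              rep("non-crosslinked", 4)))
  contacting <- sprintf("P:%d:.", 1:10)  # all Phe contact, others do not
  out <- splitByContact(labels, contacting)
  expect_equal(out$freqContacting[out$residue == "F"], 0.2)  # 2 of 10
  expect_true(is.na(out$freqContacting[out$residue == "C"]))  # no contacting Cys
  ## brute-force recount
  for (a in unique(labels$residue)) {
    sub <- labels[labels$residue == a & labels$key %in% contacting, ]
    if (nrow(sub))
      expect_equal(out$freqContacting[out$residue == a],
                   mean(sub$label == "crosslinked"))
  }
})

test_that("instance tables read from TSV with 0-based offsets", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("instance\toffsets", "i1\t2,3", "i2\t", "i3\t0"), f)
  offs <- readInstanceTable(f)
  expect_equal(offs$i1, c(2L, 3L))
  expect_equal(offs$i2, integer(0))
  expect_equal(offs$i3, 0L)
})
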