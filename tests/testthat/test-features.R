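test_that("the pinned schemas have the published column and group totals", {
  ns <- nucleotideSchema()
  expect_equal(nrow(ns), 246)
  expect_equal(length(unique(ns$group)), 15)
  expect_false(anyDuplicated(ns$name) > 0)
  as <- aaSchema()
  expect_equal(nrow(as), 36)
  ## each typed-contact group: 20 amino-acid + 6 category columns
  for (g in xlink3d:::.CONTACT_CLASSES) {
    cols <- ns$name[ns$group == g]
    expect_equal(length(cols), 26)
    expect_equal(sum(grepl("\\.cat\\.", cols)), 6)
  }
})

test_that("a contact-free nucleotide zeroes counts but keeps conformation one-hots", {
  s <- makeChiFixture("G", -120, P = 162)
  ann <- annotateInterface(s)
  v <- buildNucleotideFeatures(s, ann, "R:1:.")
  expect_equal(length(v), 246)
  ns <- nucleotideSchema()
  countCols <- ns$name[ns$group %in% c(xlink3d:::.CONTACT_CLASSES,
                                       "contact_totals",
                                       "interface_summary")]
  expect_true(all(v[countCols] == 0))
  expect_equal(unname(v["pucker.C2p_endo"]), 1)
  expect_equal(unname(v["pucker.family.S"]), 1)
  expect_equal(unname(v["orient.anti"]), 1)
})

test_that("a single Arg base-sidechain H-bond lands in the right columns", {
  s <- makeHBondFixture("U", "O2", "ARG", "NH1", 3.0)
  ann <- annotateInterface(s)
  v <- buildNucleotideFeatures(s, ann, "R:1:.")
  expect_equal(unname(v["hb_base_sidechain.R"]), 1)
  expect_equal(unname(v["hb_base_sidechain.cat.positive"]), 1)
  expect_equal(unname(v["total.hb_base_sidechain"]), 1)
  expect_equal(unname(v["n_hbonds_total"]), 1)
})

test_that("category aggregates and per-class totals are conserved sums", {
  s <- makeInterfaceFixture("UGCAUG", stackedAt = c(2, 5))
  ann <- annotateInterface(s)
  tab <- featurizeStructure(s, ann, task = "nucleotide")
  catMap <- aaCategoryMap()
  for (cc in xlink3d:::.CONTACT_CLASSES) {
    aaCols <- paste(cc, xlink3d:::.AA_LETTERS, sep = ".")
    expect_equal(tab[[paste0("total.", cc)]], rowSums(tab[, aaCols]))
    for (cat in names(catMap))
      expect_equal(tab[[paste(cc, "cat", cat, sep = ".")]],
                   rowSums(tab[, paste(cc, catMap[[cat]], sep = "."),
                               drop = FALSE]))
  }
})

test_that("amino-acid features count stacks per base with conserved totals", {
  s <- makeStackFixture("G", "PHE", 0, 3.4, 0.5)
  ann <- annotateInterface(s)
  v <- buildAAFeatures(s, ann, "P:1:.")
  expect_equal(length(v), 36)
  expect_equal(unname(v["stack.G"]), 1)
  expect_equal(unname(v["total_stacks"]), 1)
  ## an amino acid with no RNA contact is all zero
  far <- makeInterfaceFixture("UGC", stackedAt = 2)
  annF <- annotateInterface(far)
  tabA <- featurizeStructure(far, annF, task = "amino-acid")
  expect_equal(ncol(tabA), 36 + 6)
  contacting <- unique(annF@contacts$aa)
  zero <- tabA[!tabA$key %in% contacting, -(1:6)]
  if (nrow(zero)) expect_true(all(zero == 0))
})

test_that("feature values are invariant to chain and residue file order", {
  s <- makeInterfaceFixture("UGCAUG", stackedAt = c(2, 5))
  at <- atoms(s)
  ## protein chain first, residues reversed within chains
  blocks <- split(at, paste(at$chain, at$resno))
  at2 <- do.call(rbind, blocks[rev(order(names(blocks)))])
  s2 <- newComplexStructure(at2[, c("chain", "resno", "insert", "resid",
                                    "elety", "elesy", "x", "y", "z", "o",
                                    "alt")], accession = s@accession)
  t1 <- featurizeStructure(s, task = "nucleotide")
  t2 <- featurizeStructure(s2, task = "nucleotide")
  t2 <- t2[match(t1$key, t2$key), ]
  expect_equal(as.matrix(t1[, -(1:6)]), as.matrix(t2[, -(1:6)]),
               ignore_attr = TRUE)
})

test_that("identity encodings give base and overlapping dinucleotide one-hots", {
  s <- makeInterfaceFixture("UGC", stackedAt = 2)
  tab <- featurizeStructure(s, task = "nucleotide")
  enc <- encodeIdentities(tab, s)
  expect_equal(ncol(enc), ncol(tab) + 4 + 16 + 16)
  mid <- enc[enc$resno == 2, ]
  expect_equal(mid$id.base.G, 1)
  expect_equal(mid$id.left.UG, 1)
  expect_equal(mid$id.right.GC, 1)
  ## 5'-terminal: left dinucleotide block all zero
  first <- enc[enc$resno == 1, ]
  expect_equal(sum(first[, grepl("^id\\.left\\.", names(enc))]), 0)
  ## one-hot groups sum to one (or zero at terminals)
  expect_true(all(rowSums(enc[, grepl("^id\\.base\\.", names(enc))]) == 1))
})

test_that("dipeptide identity encodes the observed preceding pair", {
  s <- makeInterfaceFixture("UGCAUG", stackedAt = c(2, 5))
  at <- atoms(s)
  ## rename the two stacked PHE into GLY-PHE to get a GF dipeptide
  at$resid[at$chain == "P" & at$resno == 1] <- "GLY"
  ## GLY has no ring; keep atom names (identity encoding only reads resid)
  s2 <- newComplexStructure(at[, c("chain", "resno", "insert", "resid",
                                   "elety", "elesy", "x", "y", "z", "o",
                                   "alt")], accession = s@accession)
  tabA <- featurizeStructure(s2, task = "amino-acid")
  encA <- encodeIdentities(tabA, s2)
  phe <- encA[encA$resno == 2, ]
  expect_equal(phe$id.aa.F, 1)
  expect_equal(phe$id.pre.GF, 1)
})

test_that("feature tables round-trip through TSV with schema validation", {
  s <- makeInterfaceFixture("UGCAUG", stackedAt = c(2, 5))
  tab <- featurizeStructure(s, task = "nucleotide")
  f <- tempfile(fileext = ".tsv")
  exportFeatureTable(tab, f)
  back <- importFeatureTable(f)
  expect_equal(as.matrix(back[, -(1:6)]), as.matrix(tab[, -(1:6)]),
               ignore_attr = TRUE)
  expect_identical(attr(back, "task"), "nucleotide")
  ## truncated file -> error
  lines <- readLines(f)
  bad <- tempfile(fileext = ".tsv")
  writeLines(sub("\tstack.A", "", lines), bad)
  expect_error(importFeatureTable(bad), "column")
  ## reordered columns -> error naming the first mismatch
  swapped <- lines
  swapped[3] <- sub("^accession\tkey", "key\taccession", swapped[3])
  writeLines(swapped, bad)
  expect_error(importFeatureTable(bad), "position 1")
})
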