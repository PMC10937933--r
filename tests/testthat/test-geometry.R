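test_that("fitPlane recovers exact and perturbed planes", {
  ## three non-collinear points define an exact plane
  expect_equal(fitPlane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))$rmsd, 0)
  ## regular hexagon in z = 1
  hexagon <- cbind(cos(seq(0, 300, 60) * pi / 180),
                   sin(seq(0, 300, 60) * pi / 180), 1)
  pl <- fitPlane(hexagon)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$centroid[3], 1, tolerance = 1e-12)
  expect_equal(pl$rmsd, 0, tolerance = 1e-12)
  ## perturbed coplanar points against the eigen-decomposition oracle
  set.seed(42)
  for (rep in 1:5) {
    pts <- cbind(runif(10, -3, 3), runif(10, -3, 3), 0)
    pts[, 3] <- 0.2 * pts[, 1] - 0.1 * pts[, 2] + rnorm(10, sd = 0.01)
    expect_equal(fitPlane(pts)$normal, oraclePlaneNormal(pts),
                 tolerance = 1e-9)
  }
  expect_error(fitPlane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
})

test_that("contact calling is inclusive at the cutoff and ignores hydrogens", {
  mk <- function(d, withH = FALSE) {
    rna <- data.frame(chain = "R", resno = 1, insert = "", resid = "G",
                      elety = "N9", elesy = "N", x = 0, y = 0, z = 0,
                      o = 1, alt = "")
    aa <- data.frame(chain = "P", resno = 1, insert = "", resid = "ALA",
                     elety = c("CA", "CB"), elesy = "C",
                     x = c(d, d + 1.5), y = 0, z = 0, o = 1, alt = "")
    if (withH)
      aa <- rbind(aa, data.frame(chain = "P", resno = 1, insert = "",
                                 resid = "ALA", elety = "HA", elesy = "H",
                                 x = 1.0, y = 0, z = 0, o = 1, alt = ""))
    newComplexStructure(rbind(rna, aa))
  }
  expect_equal(nrow(heavyAtomContacts(mk(4.5))), 1)     # inclusive boundary
  expect_equal(nrow(heavyAtomContacts(mk(4.51))), 0)
  ct <- heavyAtomContacts(mk(3.0, withH = TRUE))
  expect_equal(ct$minDistance, 3.0)                     # the H at 1.0 ignored
})

test_that("contacts equal the brute-force all-pairs oracle on fixtures", {
  for (s in list(makeStackFixture("G", "PHE", 0, 3.4, 0.5),
                 makeInterfaceFixture("UGCAUG", stackedAt = c(2, 5)),
                 makeHBondFixture())) {
    got <- heavyAtomContacts(s)
    want <- oracleContacts(s)
    expect_equal(got$nt, want$nt)
    expect_equal(got$aa, want$aa)
    expect_equal(got$minDistance, want$minDistance, tolerance = 1e-9)
  }
})

test_that("hydrogen bonds are typed by moiety and gated by distance", {
  hb <- detectHBonds(makeHBondFixture("U", "OP1", "ARG", "NH1", 2.9))
  expect_equal(nrow(hb), 1)
  expect_identical(hb$rnaMoiety, "phosphate")
  expect_identical(hb$proteinMoiety, "sidechain")
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  ## same geometry beyond the cutoff
  far <- detectHBonds(makeHBondFixture("U", "OP1", "ARG", "NH1", 3.8))
  expect_equal(nrow(far), 0)
  ## backbone amine donating to a uracil base oxygen
  bb <- detectHBonds(makeHBondFixture("U", "O2", "GLY", "N", 3.0))
  expect_true(any(bb$rnaMoiety == "base" & bb$proteinMoiety == "backbone"))
})

test_that("sugar pucker recovers analytic pseudorotation phases", {
  ## analytic round trip: torsions synthesized from the cosine law
  for (target in c(162, 18)) {
    nu <- 38 * cos((target + 144 * ((0:4) - 2)) * pi / 180)
    denom <- 2 * nu[3] * (sin(36 * pi / 180) + sin(72 * pi / 180))
    P <- atan2((nu[5] + nu[2]) - (nu[4] + nu[1]), denom) * 180 / pi
    expect_equal(P %% 360, target, tolerance = 0.01)
  }
  sp <- sugarPucker(makeRibose(162, 38), "R:1:.")
  expect_equal(sp$P, 162, tolerance = 0.01)
  expect_identical(sp$puckerClass, "C2'-endo")
  expect_identical(sp$family, "S")
  sp2 <- sugarPucker(makeRibose(18, 38), "R:1:.")
  expect_identical(sp2$puckerClass, "C3'-endo")
  expect_identical(sp2$family, "N")
})

test_that("sugar pucker matches the independent dihedral-then-phase oracle", {
  rb <- makeRibose(10, 38)
  at <- atoms(rb)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rownames(xyz) <- at$elety
  expect_equal(sugarPucker(rb, "R:1:.")$P,
               oraclePhase(xyz[c("C1'", "C2'", "C3'", "C4'", "O4'"), ]),
               tolerance = 1)
})

test_that("pucker classes partition the phase wheel exactly", {
  P <- seq(0, 359.9, by = 0.1)
  cls <- xlink3d:::.puckerClass(P)
  expect_true(all(table(cls) == 360))
  expect_equal(length(unique(cls)), 10)
  ## boundary behavior: each class is a 36-degree half-open bin
  expect_identical(xlink3d:::.puckerClass(0), "C3'-endo")
  expect_identical(xlink3d:::.puckerClass(36), "C4'-exo")
  expect_identical(xlink3d:::.puckerClass(359.999), "C2'-exo")
  fam <- xlink3d:::.puckerFamily(P)
  expect_true(all(fam[P < 90 | P >= 270] == "N"))
  expect_true(all(fam[P >= 90 & P < 270] == "S"))
})

test_that("base orientation classifies syn/anti and matches the dihedral oracle", {
  f <- makeChiFixture("G", -160)
  expect_identical(baseOrientation(f, "R:1:.")$orientation, "anti")
  f <- makeChiFixture("G", 45)
  expect_identical(baseOrientation(f, "R:1:.")$orientation, "syn")
  f <- makeChiFixture("A", 180)
  bo <- baseOrientation(f, "R:1:.")
  expect_identical(bo$orientation, "anti")
  at <- atoms(f)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rownames(xyz) <- at$elety
  expect_equal(bo$chi,
               oracleDihedral(xyz["O4'", ], xyz["C1'", ], xyz["N9", ],
                              xyz["C4", ]),
               tolerance = 1e-6)
})

test_that("stacking detection honors angle, vertical and lateral gates", {
  st <- detectStacking(makeStackFixture("G", "PHE", 0, 3.4, 0.5))
  expect_equal(nrow(st), 1)
  expect_identical(st$partnerKind, "aromatic-sidechain")
  expect_equal(st$interplaneAngle, 0, tolerance = 1e-6)
  expect_equal(st$verticalSep, 3.4, tolerance = 1e-6)
  expect_equal(st$lateralOffset, 0.5, tolerance = 1e-6)
  ## tilted far beyond the angle gate
  expect_equal(nrow(detectStacking(makeStackFixture("G", "PHE", 80, 3.4,
                                                    0.5))), 0)
  ## a Gly-Ala peptide unit parallel to a uracil base
  pep <- detectStacking(makeStackFixture("U", "peptide-bond", 0, 3.5, 0.5,
                                         dipeptide = c("GLY", "ALA")))
  expect_true("peptide-bond" %in% pep$partnerKind)
  ## guanidinium partner
  gua <- detectStacking(makeStackFixture("G", "ARG", 0, 3.4, 0.5))
  expect_identical(gua$partnerKind, "guanidinium")
})

test_that("pseudo pairs need two hydrogen bonds and coplanarity", {
  pp <- detectPseudoPairs(makePseudoPairFixture(0))
  expect_equal(nrow(pp), 1)
  expect_gte(pp$nHBonds, 2)
  expect_lte(pp$verticalSep, 1.5)
  ## the same groups stacked 3.4 A apart pair no longer, but stack
  s <- makePseudoPairFixture(3.4)
  expect_equal(nrow(detectPseudoPairs(s)), 0)
  expect_gte(nrow(detectStacking(s)), 1)
  ## a single hydrogen bond is not enough
  one <- makeStackFixture("G", "ARG", 0, 0, 6)
  hb <- detectHBonds(one)
  expect_lte(nrow(hb[hb$rnaMoiety == "base", ]), 1)
  expect_equal(nrow(detectPseudoPairs(one)), 0)
})

test_that("typed interactions imply a contact record (typed-only retention)", {
  for (s in list(makeStackFixture("G", "PHE", 0, 3.4, 0.5),
                 makePseudoPairFixture(0),
                 makeHBondFixture("U", "OP1", "ARG", "NH1", 2.9))) {
    ann <- annotateInterface(s)
    pairs <- unique(rbind(ann@hbonds[, c("nt", "aa")],
                          ann@pseudoPairs[, c("nt", "aa")]))
    have <- paste(ann@contacts$nt, ann@contacts$aa)
    if (nrow(pairs))
      expect_true(all(paste(pairs$nt, pairs$aa) %in% have))
  }
})

test_that("all interface geometry is rigid-body invariant", {
  s <- makeInterfaceFixture("UGCAUG", stackedAt = c(2, 5))
  s2 <- rigidTransform(s)
  a1 <- annotateInterface(s)
  a2 <- annotateInterface(s2)
  expect_equal(a1@contacts$minDistance, a2@contacts$minDistance,
               tolerance = 1e-6)
  expect_equal(a1@stacks$interplaneAngle, a2@stacks$interplaneAngle,
               tolerance = 1e-6)
  expect_equal(a1@stacks$verticalSep, a2@stacks$verticalSep,
               tolerance = 1e-6)
  rb <- makeRibose(140, 40)
  rb2 <- rigidTransform(rb)
  expect_equal(sugarPucker(rb2, "R:1:.")$P, sugarPucker(rb, "R:1:.")$P,
               tolerance = 1e-6)
  cf <- makeChiFixture("G", -77)
  cf2 <- rigidTransform(cf)
  expect_equal(baseOrientation(cf2, "R:1:.")$chi,
               baseOrientation(cf, "R:1:.")$chi, tolerance = 1e-6)
})
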