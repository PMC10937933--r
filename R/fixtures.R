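## Synthetic structural fixtures.
##
## Idealized planar ring geometries (textbook bond lengths: 1.39 A aromatic
## C-C/C-N, 1.23 A C=O, 1.33 A guanidinium C-N) are built from internal
## coordinates so every fixture is reproducible without any template
## structure. Fixtures close the loop with the geometry module: posing a
## ring pair at a requested angle/offset and re-annotating recovers the
## requested geometry.

## ---- idealized planar moieties (local frame, plane z = 0) ----

#' @keywords internal
.ringXY <- function(names, radius, startAngle = 90, step = NULL) {
  n <- length(names)
  if (is.null(step)) step <- -360 / n
  ang <- (startAngle + step * (seq_len(n) - 1)) * pi / 180
  m <- cbind(x = radius * cos(ang), y = radius * sin(ang), z = 0)
  rownames(m) <- names
  m
}

## fused 6+5 bicycle (purines, indole): hexagon atoms in ring order; the
## pentagon shares the edge hexNames[4]-hexNames[5] and adds three atoms
## bonded 4-side first.
#' @keywords internal
.fusedBicycleXY <- function(hexNames, pentNames, bond = 1.39) {
  hex <- .ringXY(hexNames, bond)
  p4 <- hex[4, 1:2]; p5 <- hex[5, 1:2]
  mid <- (p4 + p5) / 2
  outward <- mid / sqrt(sum(mid^2))
  apo5 <- bond / (2 * tan(36 * pi / 180))
  c5 <- mid + apo5 * outward
  r5 <- bond / (2 * sin(36 * pi / 180))
  a4 <- atan2(p4[2] - c5[2], p4[1] - c5[1])
  a5 <- atan2(p5[2] - c5[2], p5[1] - c5[1])
  step <- 72 * pi / 180
  dirOK <- function(d) {
    isTRUE(all.equal(cos(a4 + 4 * d * step), cos(a5), tolerance = 1e-6)) &&
      isTRUE(all.equal(sin(a4 + 4 * d * step), sin(a5), tolerance = 1e-6))
  }
  d <- if (dirOK(1)) 1 else -1
  extra <- t(vapply(1:3, function(i) {
    a <- a4 + d * step * i
    c(c5[1] + r5 * cos(a), c5[2] + r5 * sin(a), 0)
  }, numeric(3)))
  rownames(extra) <- pentNames
  colnames(extra) <- c("x", "y", "z")
  rbind(hex, extra)
}

## substituent placed radially outward from a ring center
#' @keywords internal
.radialSub <- function(xy, atom, name, bond, center = c(0, 0)) {
  p <- xy[atom, 1:2]
  dirv <- p - center
  dirv <- dirv / sqrt(sum(dirv^2))
  m <- rbind(xy, c(p + bond * dirv, 0))
  rownames(m)[nrow(m)] <- name
  m
}

#' @keywords internal
.baseTemplate <- function(base) {
  if (base %in% c("A", "G")) {
    xy <- .fusedBicycleXY(c("N1", "C2", "N3", "C4", "C5", "C6"),
                          c("N9", "C8", "N7"))
    pentCenter <- colMeans(xy[c("C4", "C5", "N9", "C8", "N7"), 1:2])
    xy <- .radialSub(xy, "N9", "C1'", 1.47, center = pentCenter)
    if (base == "A") xy <- .radialSub(xy, "C6", "N6", 1.35)
    else {
      xy <- .radialSub(xy, "C6", "O6", 1.23)
      xy <- .radialSub(xy, "C2", "N2", 1.35)
    }
  } else {
    xy <- .ringXY(c("N1", "C2", "N3", "C4", "C5", "C6"), 1.39)
    xy <- .radialSub(xy, "N1", "C1'", 1.47)
    xy <- .radialSub(xy, "C2", "O2", 1.23)
    if (base == "C") xy <- .radialSub(xy, "C4", "N4", 1.35)
    else xy <- .radialSub(xy, "C4", "O4", 1.23)
  }
  xy
}

#' @keywords internal
.partnerTemplate <- function(partner) {
  switch(partner,
    PHE = .ringXY(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), 1.39),
    TYR = .radialSub(.ringXY(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                             1.39), "CZ", "OH", 1.36),
    TRP = .fusedBicycleXY(c("CE3", "CZ3", "CH2", "CZ2", "CE2", "CD2"),
                          c("NE1", "CD1", "CG")),
    HIS = .ringXY(c("CG", "ND1", "CE1", "NE2", "CD2"),
                  1.39 / (2 * sin(36 * pi / 180))),
    ARG = {
      m <- rbind(CZ = c(0, 0, 0),
                 NE = c(0, 1.33, 0),
                 NH1 = 1.33 * c(cos(-30 * pi / 180), sin(-30 * pi / 180), 0),
                 NH2 = 1.33 * c(cos(210 * pi / 180), sin(210 * pi / 180), 0))
      colnames(m) <- c("x", "y", "z")
      m
    },
    stop("no planar template for partner ", partner))
}

## trans-peptide unit CA_i, C_i, O_i, N_i+1, CA_i+1 in a plane
#' @keywords internal
.peptideTemplate <- function() {
  m <- rbind(
    CA1 = c(-1.52, 0.00, 0),
    C   = c(0.00, 0.00, 0),
    O   = 1.23 * c(cos(60 * pi / 180), sin(60 * pi / 180), 0),
    N   = 1.33 * c(cos(-60 * pi / 180), sin(-60 * pi / 180), 0),
    CA2 = 1.33 * c(cos(-60 * pi / 180), sin(-60 * pi / 180), 0) +
      c(1.46, 0, 0))
  colnames(m) <- c("x", "y", "z")
  m
}

#' @keywords internal
.atomsFromXYZ <- function(xyz, chain, resno, resid) {
  data.frame(chain = chain, resno = resno, insert = "",
             resid = resid, elety = rownames(xyz),
             elesy = substr(gsub("^[0-9]+", "", rownames(xyz)), 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             o = 1, alt = "", stringsAsFactors = FALSE)
}

#' Build a stacking fixture
#'
#' Poses an idealized nucleotide base below a planar partner (aromatic
#' sidechain ring, arginine guanidinium, or the peptide-bond plane of a
#' dipeptide) at a requested interplane angle, vertical separation and
#' lateral offset. At angle 0 the re-annotated geometry equals the request
#' exactly; tilted poses keep the interplane angle exact.
#'
#' @param base Nucleotide base: \code{"A"}, \code{"C"}, \code{"G"},
#'   \code{"U"}.
#' @param partner \code{"PHE"}, \code{"TYR"}, \code{"TRP"}, \code{"HIS"},
#'   \code{"ARG"}, or \code{"peptide-bond"}.
#' @param angle Interplane angle in degrees.
#' @param vertical Vertical separation in Angstrom.
#' @param lateral Lateral offset in Angstrom.
#' @param dipeptide Length-2 residue names for the peptide-bond partner
#'   (default \code{c("GLY", "ALA")}).
#' @param accession Fixture name.
#' @return A \linkS4class{ComplexStructure} with an RNA chain \code{"R"}
#'   and a protein chain \code{"P"}. Errors if the pose clashes (any
#'   cross-moiety atom pair under 1.5 Angstrom).
#' @export
makeStackFixture <- function(base, partner, angle = 0, vertical = 3.4,
                             lateral = 0, dipeptide = c("GLY", "ALA"),
                             accession = "stack-fixture") {
  baseXYZ <- .baseTemplate(base)
  ## center the base ring (not the substituents) at the origin
  ringNames <- .BASE_RING_ATOMS[[base]]
  ringCenter <- colMeans(baseXYZ[ringNames, , drop = FALSE])
  baseXYZ <- sweep(baseXYZ, 2, ringCenter)

  if (partner == "peptide-bond") {
    pXYZ <- .peptideTemplate()
  } else {
    pXYZ <- .partnerTemplate(partner)
  }
  pXYZ <- sweep(pXYZ, 2, colMeans(pXYZ))
  ## tilt about x, then place the centroid
  R <- .rotationMatrix(c(1, 0, 0), angle)
  pXYZ <- pXYZ %*% t(R)
  pXYZ <- sweep(pXYZ, 2, c(lateral, 0, vertical), "+")
  colnames(pXYZ) <- c("x", "y", "z")

  dmin <- sqrt(min(.crossDist2(baseXYZ, pXYZ)))
  if (dmin < 1.5)
    stop(sprintf("fixture not realizable: atom clash at %.2f A", dmin))

  if (partner == "peptide-bond") {
    prot <- rbind(
      .atomsFromXYZ(pXYZ[c("CA1", "C", "O"), ], "P", 1, dipeptide[1]),
      .atomsFromXYZ(pXYZ[c("N", "CA2"), ], "P", 2, dipeptide[2]))
    prot$elety <- c("CA", "C", "O", "N", "CA")
    prot$elesy <- c("C", "C", "O", "N", "C")
  } else {
    prot <- .atomsFromXYZ(pXYZ, "P", 1, partner)
  }
  rna <- .atomsFromXYZ(baseXYZ, "R", 1, base)
  newComplexStructure(rbind(rna, prot), accession = accession)
}

#' Build a hydrogen-bond fixture
#'
#' Places an amino-acid residue so a named donor/acceptor atom sits at a
#' requested distance from a named nucleotide atom, with all other
#' cross-residue atom pairs kept farther apart than the hydrogen-bond
#' cutoff.
#'
#' @param base Nucleotide base.
#' @param ntAtom Nucleotide atom name (e.g. \code{"OP1"}, \code{"O2"}).
#' @param aaResid Amino-acid residue name (e.g. \code{"ARG"}).
#' @param aaAtom Amino-acid atom name (e.g. \code{"NH1"}, backbone
#'   \code{"N"}).
#' @param distance Donor-acceptor distance in Angstrom.
#' @param accession Fixture name.
#' @return A \linkS4class{ComplexStructure}.
#' @export
makeHBondFixture <- function(base = "U", ntAtom = "OP1", aaResid = "ARG",
                             aaAtom = "NH1", distance = 2.9,
                             accession = "hbond-fixture") {
  ## nucleotide: base plane + sugar + phosphate strung out along -x
  b <- .baseTemplate(base)
  b <- sweep(b, 2, c(5, 0, 0), "+")          # base far from the interface
  sugar <- rbind("C2'" = c(11.3, 1.2, 0.5), "C3'" = c(12.5, 1.8, 0.2),
                 "C4'" = c(13.7, 1.0, 0.4), "O4'" = c(12.9, -0.2, 0.6),
                 "C5'" = c(14.9, 1.6, 0.1), "O2'" = c(11.1, 2.5, 1.1),
                 "O3'" = c(12.7, 3.1, -0.3))
  phosphate <- rbind(P = c(16.5, 1.0, 0), OP1 = c(17.5, 0.0, 0.8),
                     OP2 = c(16.9, 2.3, 0.7), "O5'" = c(16.1, 0.6, -1.4))
  colnames(sugar) <- colnames(phosphate) <- c("x", "y", "z")
  nt <- rbind(b, sugar, phosphate)

  ## amino acid: guanidinium (or backbone amine) pointing at the target
  target <- nt[ntAtom, ]
  if (!length(target)) stop("unknown nucleotide atom ", ntAtom)
  if (aaResid == "ARG" && aaAtom %in% c("NH1", "NH2", "NE")) {
    aa <- rbind(NH1 = c(0, 0, 0), CZ = c(1.33, 0, 0),
                NE = c(1.995, 1.152, 0), NH2 = c(1.995, -1.152, 0),
                CD = c(3.32, 1.2, 0), CG = c(4.1, 2.4, 0),
                CB = c(5.5, 2.3, 0), CA = c(6.2, 3.6, 0),
                N = c(7.6, 3.5, 0), C = c(6.0, 4.9, 1.0),
                O = c(6.8, 5.8, 1.2))
    ## swap labels so the requested atom is the probe at the origin
    if (aaAtom != "NH1") {
      rn <- rownames(aa)
      rn[rn == "NH1"] <- "swap"
      rn[rn == aaAtom] <- "NH1"
      rn[rn == "swap"] <- aaAtom
      rownames(aa) <- rn
    }
  } else {
    ## generic: backbone cluster with the probe atom first
    aa <- rbind(c(0, 0, 0), CA = c(1.46, 0, 0), C = c(2.0, 1.4, 0),
                O = c(1.3, 2.4, 0.2), CB = c(2.1, -1.2, 0.4))
    rownames(aa)[1] <- aaAtom
    if (aaAtom != "N") {
      aa <- rbind(aa, N = c(2.4, 0.2, -1.3))
    }
  }
  colnames(aa) <- c("x", "y", "z")
  ## direction away from the nucleotide centroid keeps everything else far
  dirv <- .unit(target - colMeans(nt))
  probe <- target + distance * dirv
  ## orient the rest of the amino acid further out along dirv: rotate the
  ## template's +x axis onto dirv
  ax <- c(1, 0, 0)
  cr <- c(ax[2] * dirv[3] - ax[3] * dirv[2],
          ax[3] * dirv[1] - ax[1] * dirv[3],
          ax[1] * dirv[2] - ax[2] * dirv[1])
  if (.vnorm(cr) < 1e-9) {
    R <- diag(3) * sign(sum(ax * dirv))
  } else {
    angle <- acos(max(-1, min(1, sum(ax * dirv)))) * 180 / pi
    R <- .rotationMatrix(cr, angle)
  }
  aaRot <- aa %*% t(R)
  aaRot <- sweep(aaRot, 2, probe, "+")
  colnames(aaRot) <- c("x", "y", "z")

  newComplexStructure(
    rbind(.atomsFromXYZ(nt, "R", 1, base),
          .atomsFromXYZ(aaRot, "P", 1, aaResid)),
    accession = accession)
}

#' Build a pseudo-pair fixture
#'
#' Poses an arginine guanidinium group coplanar with a guanine so that NH1
#' and NH2 each hydrogen-bond the O6/N7 edge of the base (the classic
#' arginine-guanine pseudo pair), at a requested out-of-plane offset
#' (0 for a coplanar pair; ~3.4 turns the same pair of groups into a
#' stack instead).
#'
#' @param vertical Out-of-plane offset of the guanidinium in Angstrom.
#' @param hbDistance Target donor-acceptor distance (default 2.9).
#' @param accession Fixture name.
#' @return A \linkS4class{ComplexStructure}.
#' @export
makePseudoPairFixture <- function(vertical = 0, hbDistance = 2.9,
                                  accession = "pseudopair-fixture") {
  baseXYZ <- .baseTemplate("G")
  ringNames <- .BASE_RING_ATOMS[["G"]]
  ringCenter <- colMeans(baseXYZ[ringNames, , drop = FALSE])
  o6 <- baseXYZ["O6", ]; n7 <- baseXYZ["N7", ]
  mid <- (o6 + n7) / 2
  dirv <- .unit(mid - ringCenter)
  axis <- .unit(n7 - o6)
  u <- -dirv                      # toward the base edge
  guan <- function(t) {
    cz <- mid + t * dirv + c(0, 0, vertical)
    m <- rbind(CZ = cz,
               NE = cz - 1.33 * u,
               NH1 = cz + 1.33 * (u * cos(pi / 3) - axis * sin(pi / 3)),
               NH2 = cz + 1.33 * (u * cos(pi / 3) + axis * sin(pi / 3)))
    colnames(m) <- c("x", "y", "z")
    m
  }
  cost <- function(t) {
    m <- guan(t)
    (.vnorm(m["NH1", ] - o6) - hbDistance)^2 +
      (.vnorm(m["NH2", ] - n7) - hbDistance)^2
  }
  t0 <- stats::optimize(cost, c(0.5, 8))$minimum
  g <- guan(t0)
  newComplexStructure(
    rbind(.atomsFromXYZ(baseXYZ, "R", 1, "G"),
          .atomsFromXYZ(g, "P", 1, "ARG")),
    accession = accession)
}

#' Build a ribose posed at a target pseudorotation phase
#'
#' Constructs a five-membered ribose ring whose endocyclic torsions realize
#' a requested pseudorotation phase P and amplitude tau_m: in-plane pentagon
#' coordinates get out-of-plane displacements z_j = q cos(phi + 4 pi j / 5),
#' and (phi, q) are solved numerically so the recovered (P, tau_m) match
#' the target (P within 1 degree across the full phase wheel). C5' and O2'
#' substituents are attached so the residue classifies as a ribonucleotide.
#'
#' @param P Target pseudorotation phase in degrees, [0, 360).
#' @param tauM Target puckering amplitude in degrees, in (20, 50).
#' @param base Residue name for the ring (default \code{"U"}; no base atoms
#'   are built).
#' @param accession Fixture name.
#' @return A \linkS4class{ComplexStructure} with one RNA residue.
#' @export
makeRibose <- function(P, tauM = 38, base = "U", accession = "ribose") {
  stopifnot(tauM > 20, tauM < 50)
  ringNames <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  radius <- 1.52 / (2 * sin(36 * pi / 180))
  flat <- .ringXY(ringNames, radius)

  buildRing <- function(par) {
    z <- par[2] * cos((par[1] + 144 * (0:4)) * pi / 180)
    m <- flat
    m[, 3] <- z
    m
  }
  recovered <- function(par) {
    m <- buildRing(par)
    tor <- function(a, b, c, d)
      .dihedral(m[a, ], m[b, ], m[c, ], m[d, ])
    nu <- c(tor("C4'", "O4'", "C1'", "C2'"),
            tor("O4'", "C1'", "C2'", "C3'"),
            tor("C1'", "C2'", "C3'", "C4'"),
            tor("C2'", "C3'", "C4'", "O4'"),
            tor("C3'", "C4'", "O4'", "C1'"))
    .phaseFromNu(nu)
  }
  objective <- function(par) {
    if (par[2] < 0.05 || par[2] > 1.2) return(1e6)
    got <- recovered(par)
    dP <- (got$P - P + 180) %% 360 - 180
    dP^2 + (got$tauM - tauM)^2
  }
  ## coarse phase scan then local refinement
  amp0 <- tauM / 105   # rough torsion-to-displacement scaling
  starts <- seq(0, 350, by = 30)
  vals <- vapply(starts, function(s) objective(c(s, amp0)), numeric(1))
  best <- stats::optim(c(starts[which.min(vals)], amp0), objective,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  ring <- buildRing(best$par)

  ## substituents off the ring plane (do not affect the nu torsions)
  sub <- function(atom, name, bond) {
    p <- ring[atom, ]
    dirv <- .unit(c(p[1], p[2], 0))
    out <- p + bond * (dirv + c(0, 0, 0.35)) / .vnorm(dirv + c(0, 0, 0.35))
    out
  }
  extra <- rbind("C5'" = sub("C4'", "C5'", 1.51),
                 "O2'" = sub("C2'", "O2'", 1.41))
  xyz <- rbind(ring, extra)
  colnames(xyz) <- c("x", "y", "z")
  newComplexStructure(.atomsFromXYZ(xyz, "R", 1, base),
                      accession = accession)
}

## In-plane rigid placement of a C base so its Watson-Crick edge faces a
## G at hydrogen-bonding distance (N4...O6, N3...N1, O2...N2 = 2.9 A).
#' @keywords internal
.wcPairCTemplate <- function(hb = 2.9) {
  g <- .baseTemplate("G")
  cT <- .baseTemplate("C")
  place <- function(par) {
    R <- .rotationMatrix(c(0, 0, 1), par[1])
    sweep(cT %*% t(R), 2, c(par[2], par[3], 0), "+")
  }
  cost <- function(par) {
    m <- place(par)
    (.vnorm(m["N4", ] - g["O6", ]) - hb)^2 +
      (.vnorm(m["N3", ] - g["N1", ]) - hb)^2 +
      (.vnorm(m["O2", ] - g["N2", ]) - hb)^2
  }
  best <- NULL
  for (a0 in seq(0, 330, by = 30)) {
    fit <- stats::optim(c(a0, 6, 0), cost, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  place(best$par)
}

#' Build a single-stranded RNA fixture
#'
#' A chain of bases spaced far apart: no base pairs, no stacking; every
#' nucleotide annotates as unpaired single strand.
#'
#' @param sequence Base string (e.g. \code{"UGCAUGU"}).
#' @param accession Fixture name.
#' @return A \linkS4class{ComplexStructure}.
#' @export
makeSingleStrandFixture <- function(sequence = "UGCAUGU",
                                    accession = "ss-fixture") {
  basesVec <- strsplit(sequence, "")[[1]]
  rows <- lapply(seq_along(basesVec), function(i) {
    xyz <- sweep(.baseTemplate(basesVec[i]), 2, c(12 * (i - 1), 0, 0), "+")
    .atomsFromXYZ(xyz, "R", i, basesVec[i])
  })
  newComplexStructure(do.call(rbind, rows), accession = accession)
}

#' Build a multi-residue interface fixture
#'
#' A single-stranded RNA chain (bases spaced apart) with phenylalanine
#' rings stacked (0 degrees, 3.4 Angstrom, small offset) over chosen
#' positions: a minimal complex in which some nucleotides contact protein
#' and some do not, for exercising the labeling and classification path
#' end to end.
#'
#' @param sequence Base string.
#' @param stackedAt 1-based positions that get a stacked Phe.
#' @param accession Fixture name.
#' @return A \linkS4class{ComplexStructure} with chains \code{"R"} and
#'   \code{"P"}.
#' @export
makeInterfaceFixture <- function(sequence = "UGCAUGU", stackedAt = c(2, 6),
                                 accession = "interface-fixture") {
  basesVec <- strsplit(sequence, "")[[1]]
  rna <- lapply(seq_along(basesVec), function(i) {
    xyz <- .baseTemplate(basesVec[i])
    ringCenter <- colMeans(xyz[.BASE_RING_ATOMS[[basesVec[i]]], ,
                               drop = FALSE])
    xyz <- sweep(xyz, 2, ringCenter)
    .atomsFromXYZ(sweep(xyz, 2, c(12 * (i - 1), 0, 0), "+"),
                  "R", i, basesVec[i])
  })
  prot <- lapply(seq_along(stackedAt), function(j) {
    ring <- .partnerTemplate("PHE")
    ring <- sweep(ring, 2, colMeans(ring))
    ring <- sweep(ring, 2, c(12 * (stackedAt[j] - 1) + 0.5, 0, 3.4), "+")
    .atomsFromXYZ(ring, "P", j, "PHE")
  })
  newComplexStructure(do.call(rbind, c(rna, prot)), accession = accession)
}

#' Build a hairpin fixture (4-bp G-C stem, 4-nt loop)
#'
#' Four stacked Watson-Crick G-C pairs (3.6 Angstrom rise, so cross-level
#' atoms stay beyond hydrogen-bond range while stem neighbors stack) closed
#' by four spatially separated loop bases. Residues 1-4 pair with residues
#' 12-9; residues 5-8 form the hairpin loop.
#'
#' @param loop Loop base string (default \code{"UUUU"}).
#' @param accession Fixture name.
#' @return A \linkS4class{ComplexStructure} with one 12-nt RNA chain.
#' @export
makeHairpinFixture <- function(loop = "UUUU", accession = "hairpin") {
  g <- .baseTemplate("G")
  cT <- .wcPairCTemplate()
  rise <- 3.6
  rows <- vector("list", 12)
  for (lev in 1:4) {
    dz <- c(0, 0, (lev - 1) * rise)
    rows[[lev]] <- .atomsFromXYZ(sweep(g, 2, dz, "+"), "R", lev, "G")
    rows[[13 - lev]] <- .atomsFromXYZ(sweep(cT, 2, dz, "+"),
                                      "R", 13 - lev, "C")
  }
  loopBases <- strsplit(loop, "")[[1]]
  stopifnot(length(loopBases) == 4)
  for (i in seq_along(loopBases)) {
    dz <- c(25 + 12 * i, 20, 10)
    rows[[4 + i]] <- .atomsFromXYZ(sweep(.baseTemplate(loopBases[i]), 2,
                                         dz, "+"),
                                   "R", 4 + i, loopBases[i])
  }
  newComplexStructure(do.call(rbind, rows), accession = accession)
}

#' Build a nucleotide fixture posed at a target glycosidic torsion
#'
#' Attaches an idealized base to a ribose ring so that the glycosidic
#' torsion (O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines)
#' equals a requested chi.
#'
#' @param base Nucleotide base.
#' @param chi Target glycosidic torsion in degrees, (-180, 180].
#' @param P Ribose pseudorotation phase (default 18, C3'-endo).
#' @param tauM Puckering amplitude (default 38).
#' @param accession Fixture name.
#' @return A \linkS4class{ComplexStructure} with one RNA residue carrying
#'   both the sugar ring and the base.
#' @export
makeChiFixture <- function(base = "G", chi = -120, P = 18, tauM = 38,
                           accession = "chi-fixture") {
  sugar <- makeRibose(P, tauM, base = base, accession = accession)
  at <- atoms(sugar)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rownames(xyz) <- at$elety
  c1 <- xyz["C1'", ]; o4 <- xyz["O4'", ]

  ## glycosidic nitrogen off C1' at a tetrahedral angle from O4'
  e1 <- .unit(c1 - o4)
  p <- .unit(c(-e1[2], e1[1], 0))
  if (.vnorm(c(-e1[2], e1[1], 0)) < 1e-6) p <- c(1, 0, 0)
  th <- 109.5 * pi / 180
  nPos <- c1 + 1.47 * (-e1 * cos(th) + p * sin(th))

  tmpl <- .baseTemplate(base)
  glyN <- if (base %in% c("A", "G")) "N9" else "N1"
  ref <- if (base %in% c("A", "G")) "C4" else "C2"
  ## map template glycosidic bond onto the built one
  vT <- .unit(tmpl["C1'", ] - tmpl[glyN, ])
  vS <- .unit(c1 - nPos)
  cr <- c(vT[2] * vS[3] - vT[3] * vS[2],
          vT[3] * vS[1] - vT[1] * vS[3],
          vT[1] * vS[2] - vT[2] * vS[1])
  R0 <- if (.vnorm(cr) < 1e-9) diag(3) * sign(sum(vT * vS)) else
    .rotationMatrix(cr, acos(max(-1, min(1, sum(vT * vS)))) * 180 / pi)
  baseXYZ <- sweep(tmpl, 2, tmpl[glyN, ]) %*% t(R0)
  baseXYZ <- sweep(baseXYZ, 2, nPos, "+")
  ## spin about the glycosidic bond to hit the target chi
  cur <- .dihedral(o4, c1, baseXYZ[glyN, ], baseXYZ[ref, ])
  Rspin <- .rotationMatrix(c1 - nPos, chi - cur)
  baseXYZ <- sweep(sweep(baseXYZ, 2, nPos) %*% t(Rspin), 2, nPos, "+")
  baseXYZ <- baseXYZ[setdiff(rownames(baseXYZ), "C1'"), , drop = FALSE]
  colnames(baseXYZ) <- c("x", "y", "z")

  newComplexStructure(
    rbind(at[, c("chain", "resno", "insert", "resid", "elety", "elesy",
                 "x", "y", "z", "o", "alt")],
          .atomsFromXYZ(baseXYZ, "R", 1, base)),
    accession = accession)
}

#' Simulate a labeled feature table with injected signal
#'
#' Emulates the labeled interface feature tables used for classification:
#' count features are Poisson at a baseline rate, a chosen subset is
#' informative with logistic effect sizes beta, and labels are Bernoulli
#' with log-odds intercept + beta . x. Defaults reproduce the
#' nucleotide-task imbalance regime (43 positive : 171 negative expected).
#'
#' @param nPos,nNeg Expected class sizes; the total row count is
#'   \code{nPos + nNeg} and the intercept is \code{qlogis(nPos / n)}.
#' @param nFeatures Number of count features (default 246).
#' @param informative Indices of informative features (default the first
#'   5).
#' @param beta Effect size per informative feature on the log-odds scale
#'   (default 1.2).
#' @param baselineRate Poisson rate of null count features (default 0.3).
#' @param informativeRate Poisson rate of informative features (default
#'   1.0, giving them dynamic range to carry signal).
#' @param seed RNG seed.
#' @return List: \code{x} (matrix), \code{y} (0/1), \code{informative},
#'   \code{beta}, \code{intercept}, \code{logOdds} (true generative
#'   log-odds per row, usable as a Bayes-optimal score).
#' @export
simulateFeatureTable <- function(nPos = 43, nNeg = 171, nFeatures = 246,
                                 informative = 1:5, beta = 1.2,
                                 baselineRate = 0.3, informativeRate = 1.0,
                                 seed = 1) {
  n <- nPos + nNeg
  target <- nPos / n
  .withSeed(seed, {
    x <- matrix(stats::rpois(n * nFeatures, baselineRate), n, nFeatures)
    if (length(informative))
      x[, informative] <- stats::rpois(n * length(informative),
                                       informativeRate)
    colnames(x) <- sprintf("f%03d", seq_len(nFeatures))
    b <- numeric(nFeatures)
    b[informative] <- beta
    signal <- as.numeric(x %*% b)
    ## calibrate the intercept so the expected label rate over the realized
    ## rows equals the target imbalance (the raw logit overshoots once the
    ## signal has variance)
    intercept <- if (all(signal == signal[1])) {
      stats::qlogis(target) - signal[1]
    } else {
      stats::uniroot(function(b0)
        mean(stats::plogis(b0 + signal)) - target,
        lower = -50, upper = 50)$root
    }
    lo <- intercept + signal
    y <- stats::rbinom(n, 1, stats::plogis(lo))
    list(x = x, y = y, informative = informative, beta = b,
         intercept = intercept, logOdds = lo)
  })
}
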