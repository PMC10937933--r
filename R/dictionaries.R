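## Pinned residue and atom dictionaries.
##
## Everything that downstream annotation depends on (residue kinds, moiety
## membership, hydrogen-bond capabilities, planar-group atom sets, amino-acid
## categories) is defined here once so that feature extraction is reproducible
## and independent of the input file's conventions.

#' @keywords internal
.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.RNA_BASES <- c("A", "C", "G", "U")
.DNA_RES <- c("DA", "DC", "DG", "DT")

## Modified-residue aliases mapped to parent residues. Unmapped modified
## residues get kind "other" and are excluded from feature tables.
.RES_ALIASES <- c(
  PSU = "U", H2U = "U", "4SU" = "U", OMU = "U", "5MU" = "U", DHU = "U",
  "5MC" = "C", OMC = "C",
  "1MA" = "A", MA6 = "A", OMA = "A",
  "2MG" = "G", "7MG" = "G", M2G = "G", OMG = "G", "1MG" = "G",
  MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR"
)

#' Resolve a residue name to its parent standard residue
#' @keywords internal
.canonicalResid <- function(resid) {
  resid <- toupper(trimws(resid))
  hit <- unname(.RES_ALIASES[resid])
  unname(ifelse(is.na(hit), resid, hit))
}

#' Residue kind from (canonicalized) residue name
#' @keywords internal
.residueKind <- function(resid) {
  resid <- .canonicalResid(resid)
  kind <- rep("other", length(resid))
  kind[resid %in% names(.AA3)] <- "amino-acid"
  kind[resid %in% .RNA_BASES] <- "ribonucleotide"
  kind[resid %in% .DNA_RES] <- "deoxynucleotide"
  kind
}

## RNA moiety membership (primes normalized to ASCII quote in atom names).
.PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O5'", "O3'")
.SUGAR_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'")

#' RNA moiety of an atom name: base, sugar or phosphate
#' @keywords internal
.rnaMoiety <- function(elety) {
  out <- rep("base", length(elety))
  out[elety %in% .SUGAR_ATOMS] <- "sugar"
  out[elety %in% .PHOSPHATE_ATOMS] <- "phosphate"
  out
}

.PROT_BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Protein moiety of an atom name: backbone or sidechain
#' @keywords internal
.proteinMoiety <- function(elety) {
  ifelse(elety %in% .PROT_BACKBONE, "backbone", "sidechain")
}

## Hydrogen-bond capability tables (heavy-atom only; no explicit hydrogens).
## Values: "d" donor, "a" acceptor, "da" both.
.PROT_HB <- list(
  backbone = c(N = "d", O = "a", OXT = "a"),
  ARG = c(NE = "d", NH1 = "d", NH2 = "d"),
  LYS = c(NZ = "d"),
  SER = c(OG = "da"),
  THR = c(OG1 = "da"),
  TYR = c(OH = "da"),
  ASN = c(ND2 = "d", OD1 = "a"),
  GLN = c(NE2 = "d", OE1 = "a"),
  HIS = c(ND1 = "da", NE2 = "da"),
  ASP = c(OD1 = "a", OD2 = "a"),
  GLU = c(OE1 = "a", OE2 = "a"),
  TRP = c(NE1 = "d")
)

.RNA_HB_COMMON <- c(OP1 = "a", OP2 = "a", OP3 = "a", "O5'" = "a",
                    "O3'" = "a", "O4'" = "a", "O2'" = "da")
.RNA_HB_BASE <- list(
  A = c(N6 = "d", N1 = "a", N3 = "a", N7 = "a"),
  G = c(N1 = "d", N2 = "d", O6 = "a", N3 = "a", N7 = "a"),
  C = c(N4 = "d", N3 = "a", O2 = "a"),
  U = c(N3 = "d", O2 = "a", O4 = "a")
)

#' Hydrogen-bond capability ("d","a","da" or NA) for one atom
#' @keywords internal
.hbCapability <- function(resid, elety) {
  resid <- .canonicalResid(resid)
  n <- length(resid)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (resid[i] %in% names(.AA3)) {
      cap <- .PROT_HB$backbone[elety[i]]
      if (is.na(cap) && !is.null(.PROT_HB[[resid[i]]]))
        cap <- .PROT_HB[[resid[i]]][elety[i]]
      out[i] <- unname(cap)
    } else if (resid[i] %in% .RNA_BASES) {
      cap <- .RNA_HB_COMMON[elety[i]]
      if (is.na(cap)) cap <- .RNA_HB_BASE[[resid[i]]][elety[i]]
      out[i] <- unname(cap)
    }
  }
  out
}

## Planar moiety atom sets used for stacking / pseudo-pair plane fits.
.BASE_RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.SIDECHAIN_PLANES <- list(
  PHE = list(kind = "aromatic-sidechain",
             atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(kind = "aromatic-sidechain",
             atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(kind = "aromatic-sidechain",
             atoms = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                       "CZ2", "CZ3", "CH2")),
  HIS = list(kind = "aromatic-sidechain",
             atoms = c("CG", "ND1", "CD2", "CE1", "NE2")),
  ARG = list(kind = "guanidinium",
             atoms = c("NE", "CZ", "NH1", "NH2"))
)

## Planar sidechain groups that can form pseudo base pairs (coplanar,
## multiply hydrogen-bonded): guanidinium, amide, carboxyl, His ring,
## aromatic rings.
.PSEUDOPAIR_PLANES <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"),
  GLN = c("CD", "OE1", "NE2"),
  ASP = c("CG", "OD1", "OD2"),
  GLU = c("CD", "OE1", "OE2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

#' Amino-acid category map
#'
#' Maps each of the 20 standard amino acids (one-letter code) to its
#' physicochemical categories. Overlaps are deliberate (e.g. His is polar,
#' positive and aromatic); category aggregates in the feature tables are
#' sums over member amino acids.
#'
#' @return A named list: category name -> character vector of one-letter
#'   amino-acid codes.
#' @examples
#' aaCategoryMap()$aromatic
#' @export
aaCategoryMap <- function() {
  list(
    polar       = c("S", "T", "N", "Q", "Y", "C", "H"),
    positive    = c("R", "K", "H"),
    negative    = c("D", "E"),
    hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C", "P"),
    aromatic    = c("F", "W", "Y", "H"),
    aliphatic   = c("A", "V", "L", "I")
  )
}

.PUCKER_CLASSES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo",
                     "C2'-endo", "C3'-exo", "C4'-endo", "O4'-exo",
                     "C1'-endo", "C2'-exo")

.SS_ELEMENTS <- c("helix-internal", "helix-end", "hairpin-loop",
                  "internal-loop", "bulge", "junction",
                  "terminal-ss", "isolated-ss")
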