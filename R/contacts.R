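## Heavy-atom contacts across the protein-RNA interface.

#' Contact configuration
#'
#' @param heavyAtomCutoff Inclusive heavy-atom distance cutoff in Angstrom
#'   defining a direct nucleotide-amino-acid contact (default 4.5).
#' @param hbCutoff Donor-acceptor heavy-atom cutoff for hydrogen bonds
#'   (default 3.5 Angstrom).
#' @param stackAngle Maximum acute interplane angle for stacking (degrees,
#'   default 30).
#' @param stackVertical Allowed vertical separation range for stacking
#'   (Angstrom, default c(2.0, 4.5)).
#' @param stackLateral Maximum lateral offset for stacking (Angstrom,
#'   default 3.0).
#' @param pairVertical Maximum vertical separation for a coplanar pseudo
#'   pair (Angstrom, default 1.5).
#' @return A named list of thresholds used throughout annotation.
#' @export
contactConfig <- function(heavyAtomCutoff = 4.5, hbCutoff = 3.5,
                          stackAngle = 30, stackVertical = c(2.0, 4.5),
                          stackLateral = 3.0, pairVertical = 1.5) {
  stopifnot(heavyAtomCutoff > 0, hbCutoff > 0, stackAngle > 0,
            length(stackVertical) == 2, stackVertical[1] >= 0,
            stackVertical[2] > stackVertical[1], stackLateral > 0,
            pairVertical > 0)
  list(heavyAtomCutoff = heavyAtomCutoff, hbCutoff = hbCutoff,
       stackAngle = stackAngle, stackVertical = stackVertical,
       stackLateral = stackLateral, pairVertical = pairVertical)
}

## Residue-indexed heavy atoms for one polymer side of the interface.
#' @keywords internal
.sideAtoms <- function(structure, classes, kinds) {
  cls <- chainClasses(structure)
  at <- atoms(structure, heavyOnly = TRUE)
  at <- at[cls[at$chain] %in% classes & at$kind %in% kinds, , drop = FALSE]
  at$key <- .resKey(at$chain, at$resno, at$insert)
  at
}

#' Heavy-atom contacts between nucleotides and amino acids
#'
#' One record per (nucleotide, amino acid) pair whose minimum heavy-atom
#' distance is at or below the cutoff (inclusive); hydrogens are excluded.
#' The search is complete: every cross-interface pair is examined.
#'
#' @param structure A \linkS4class{ComplexStructure} with at least one RNA
#'   and one protein chain.
#' @param config \code{contactConfig()} thresholds.
#' @return data.frame with columns \code{nt}, \code{aa} (residue keys),
#'   \code{ntBase}, \code{aaName} (canonical names), \code{minDistance}.
#' @export
heavyAtomContacts <- function(structure, config = contactConfig()) {
  rna <- .sideAtoms(structure, "RNA", "ribonucleotide")
  prot <- .sideAtoms(structure, "protein", "amino-acid")
  empty <- data.frame(nt = character(), aa = character(),
                      ntBase = character(), aaName = character(),
                      minDistance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(rna) || !nrow(prot)) return(empty)
  d2 <- .crossDist2(as.matrix(rna[, c("x", "y", "z")]),
                    as.matrix(prot[, c("x", "y", "z")]))
  cut2 <- config$heavyAtomCutoff^2
  hit <- which(d2 <= cut2 + 1e-9, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  pair <- paste(rna$key[hit[, 1]], prot$key[hit[, 2]], sep = "\r")
  mind <- tapply(sqrt(d2[hit]), pair, min)
  parts <- strsplit(names(mind), "\r", fixed = TRUE)
  nt <- vapply(parts, `[`, "", 1)
  aa <- vapply(parts, `[`, "", 2)
  out <- data.frame(
    nt = nt, aa = aa,
    ntBase = .canonicalResid(rna$resid[match(nt, rna$key)]),
    aaName = .canonicalResid(prot$resid[match(aa, prot$key)]),
    minDistance = as.numeric(mind),
    stringsAsFactors = FALSE)
  out <- out[order(out$nt, out$aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Squared cross-distance matrix (rows of a x rows of b).
#' @keywords internal
.crossDist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
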