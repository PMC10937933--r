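## Typed hydrogen bonds across the protein-RNA interface.
##
## Hydrogen positions are not required: a bond is called when a donor-capable
## and an acceptor-capable heavy atom (N/O, per the pinned capability tables)
## lie within the cutoff, matching how most deposited structures (which lack
## hydrogens) have to be analyzed.

#' Detect protein-RNA hydrogen bonds
#'
#' Calls donor-acceptor heavy-atom pairs within \code{config$hbCutoff} and
#' types each bond by the RNA moiety of the nucleotide atom (base, sugar or
#' phosphate, per the pinned atom lists) and the protein moiety of the
#' amino-acid atom (sidechain or backbone). Atoms with unknown hydrogen-bond
#' capability are skipped.
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @param config \code{contactConfig()} thresholds.
#' @return data.frame with columns \code{nt}, \code{aa}, \code{ntBase},
#'   \code{aaName}, \code{ntAtom}, \code{aaAtom}, \code{distance},
#'   \code{rnaMoiety}, \code{proteinMoiety}, \code{donorSide} ("rna" or
#'   "protein").
#' @export
detectHBonds <- function(structure, config = contactConfig()) {
  rna <- .sideAtoms(structure, "RNA", "ribonucleotide")
  prot <- .sideAtoms(structure, "protein", "amino-acid")
  empty <- data.frame(nt = character(), aa = character(),
                      ntBase = character(), aaName = character(),
                      ntAtom = character(), aaAtom = character(),
                      distance = numeric(), rnaMoiety = character(),
                      proteinMoiety = character(), donorSide = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(rna) || !nrow(prot)) return(empty)
  rna$cap <- .hbCapability(rna$resid, rna$elety)
  prot$cap <- .hbCapability(prot$resid, prot$elety)
  rna <- rna[!is.na(rna$cap), , drop = FALSE]
  prot <- prot[!is.na(prot$cap), , drop = FALSE]
  if (!nrow(rna) || !nrow(prot)) return(empty)
  d2 <- .crossDist2(as.matrix(rna[, c("x", "y", "z")]),
                    as.matrix(prot[, c("x", "y", "z")]))
  hit <- which(d2 <= config$hbCutoff^2 + 1e-9, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  rnaDonates <- grepl("d", rna$cap[i]) & grepl("a", prot$cap[j])
  protDonates <- grepl("d", prot$cap[j]) & grepl("a", rna$cap[i])
  keep <- rnaDonates | protDonates
  if (!any(keep)) return(empty)
  i <- i[keep]; j <- j[keep]
  out <- data.frame(
    nt = rna$key[i], aa = prot$key[j],
    ntBase = .canonicalResid(rna$resid[i]),
    aaName = .canonicalResid(prot$resid[j]),
    ntAtom = rna$elety[i], aaAtom = prot$elety[j],
    distance = sqrt(d2[cbind(i, j)]),
    rnaMoiety = .rnaMoiety(rna$elety[i]),
    proteinMoiety = .proteinMoiety(prot$elety[j]),
    donorSide = ifelse(protDonates[keep], "protein", "rna"),
    stringsAsFactors = FALSE)
  out <- out[order(out$nt, out$aa, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Base-base hydrogen bonds within RNA, used for pairing-context calls.
#' @keywords internal
.baseBaseHBonds <- function(structure, cutoff = 3.5) {
  rna <- .sideAtoms(structure, "RNA", "ribonucleotide")
  empty <- data.frame(nt1 = character(), nt2 = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(rna)) return(empty)
  rna$cap <- .hbCapability(rna$resid, rna$elety)
  base <- rna[!is.na(rna$cap) & .rnaMoiety(rna$elety) == "base", ,
              drop = FALSE]
  if (nrow(base) < 2) return(empty)
  d2 <- .crossDist2(as.matrix(base[, c("x", "y", "z")]),
                    as.matrix(base[, c("x", "y", "z")]))
  hit <- which(d2 <= cutoff^2 + 1e-9 & upper.tri(d2), arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  ok <- base$key[i] != base$key[j] &
    ((grepl("d", base$cap[i]) & grepl("a", base$cap[j])) |
     (grepl("a", base$cap[i]) & grepl("d", base$cap[j])))
  if (!any(ok)) return(empty)
  data.frame(nt1 = base$key[i][ok], nt2 = base$key[j][ok],
             distance = sqrt(d2[cbind(i, j)])[ok],
             stringsAsFactors = FALSE)
}
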