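## Planar stacking and pseudo base pairing.
##
## Geometry convention: for two fitted planes, the interplane angle is the
## acute angle between normals; the centroid-centroid vector is projected
## onto the averaged normal (normals co-oriented first) to give the vertical
## separation, and the remainder is the lateral offset.

## Catalog of planar moieties in a structure. One row per moiety with a
## fitted plane; degenerate moieties are skipped with a warning.
#' @keywords internal
.planarMoieties <- function(structure) {
  out <- list()
  cls <- chainClasses(structure)
  res <- residueTable(structure)

  addMoiety <- function(key, kind, partner, atomNames, at) {
    xyz <- .atomXYZ(at, atomNames)
    if (is.null(xyz)) return()
    pl <- tryCatch(fitPlane(xyz), error = function(e) {
      warning("degenerate plane for ", partner, " (", key, "); skipped")
      NULL
    })
    if (is.null(pl)) return()
    out[[length(out) + 1]] <<- list(key = key, kind = kind,
                                    partner = partner,
                                    centroid = pl$centroid,
                                    normal = pl$normal)
  }

  ## nucleotide base rings
  ntRes <- res[res$kind == "ribonucleotide" & cls[res$chain] == "RNA", ,
               drop = FALSE]
  for (i in seq_len(nrow(ntRes))) {
    base <- ntRes$canonical[i]
    if (!base %in% names(.BASE_RING_ATOMS)) next
    addMoiety(ntRes$key[i], "nucleotide-base", ntRes$key[i],
              .BASE_RING_ATOMS[[base]],
              .residueAtoms(structure, ntRes$key[i]))
  }

  ## aromatic / guanidinium sidechain planes
  aaRes <- res[res$kind == "amino-acid" & cls[res$chain] == "protein", ,
               drop = FALSE]
  for (i in seq_len(nrow(aaRes))) {
    spec <- .SIDECHAIN_PLANES[[aaRes$canonical[i]]]
    if (is.null(spec)) next
    addMoiety(aaRes$key[i], spec$kind, aaRes$key[i], spec$atoms,
              .residueAtoms(structure, aaRes$key[i]))
  }

  ## peptide-bond planes (CA_i, C_i, O_i, N_i+1, CA_i+1) for bonded
  ## consecutive residues
  for (ch in names(cls)[cls == "protein"]) {
    sub <- aaRes[aaRes$chain == ch, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      a1 <- .residueAtoms(structure, sub$key[i])
      a2 <- .residueAtoms(structure, sub$key[i + 1])
      c1 <- .atomXYZ(a1, "C"); n2 <- .atomXYZ(a2, "N")
      if (is.null(c1) || is.null(n2)) next
      if (.vnorm(c1[1, ] - n2[1, ]) > 2.0) next  # not peptide-bonded
      x1 <- .atomXYZ(a1, c("CA", "C", "O"))
      x2 <- .atomXYZ(a2, c("N", "CA"))
      if (is.null(x1) || is.null(x2)) next
      pl <- tryCatch(fitPlane(rbind(x1, x2)), error = function(e) NULL)
      if (is.null(pl)) next
      out[[length(out) + 1]] <- list(
        key = paste(sub$key[i], sub$key[i + 1], sep = "+"),
        kind = "peptide-bond",
        partner = paste(sub$key[i], sub$key[i + 1], sep = "+"),
        centroid = pl$centroid, normal = pl$normal)
    }
  }
  out
}

## Stacking geometry between two planes.
#' @keywords internal
.stackGeometry <- function(p1, p2) {
  angle <- .interplaneAngle(p1$normal, p2$normal)
  n2 <- p2$normal
  if (sum(p1$normal * n2) < 0) n2 <- -n2
  navg <- .unit(p1$normal + n2)
  d <- p2$centroid - p1$centroid
  vertical <- abs(sum(d * navg))
  lateral <- sqrt(max(0, sum(d * d) - vertical^2))
  list(angle = angle, vertical = vertical, lateral = lateral)
}

#' Detect planar stacking on nucleotide bases
#'
#' Finds stacking partners of every RNA base among aromatic side chains
#' (Phe, Tyr, Trp, His), arginine guanidinium groups, peptide-bond planes of
#' consecutive residues, and other nucleotide bases. A record is emitted iff
#' the acute interplane angle is at most \code{config$stackAngle}, the
#' vertical separation lies in \code{config$stackVertical} and the lateral
#' offset is at most \code{config$stackLateral}.
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @param config \code{contactConfig()} thresholds.
#' @param partners Partner kinds to search (default all four).
#' @return data.frame with columns \code{nt}, \code{partnerKind},
#'   \code{partner}, \code{interplaneAngle}, \code{verticalSep},
#'   \code{lateralOffset}.
#' @export
detectStacking <- function(structure, config = contactConfig(),
                           partners = c("aromatic-sidechain", "guanidinium",
                                        "peptide-bond", "nucleotide-base")) {
  moieties <- .planarMoieties(structure)
  empty <- data.frame(nt = character(), partnerKind = character(),
                      partner = character(), interplaneAngle = numeric(),
                      verticalSep = numeric(), lateralOffset = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(moieties)) return(empty)
  kinds <- vapply(moieties, `[[`, "", "kind")
  bases <- which(kinds == "nucleotide-base")
  cand <- which(kinds %in% partners)
  rows <- list()
  for (b in bases) {
    for (p in cand) {
      if (p == b) next
      ## base-base records only once per unordered pair unless asked per-base
      g <- .stackGeometry(moieties[[b]], moieties[[p]])
      if (g$angle <= config$stackAngle + 1e-9 &&
          g$vertical >= config$stackVertical[1] - 1e-9 &&
          g$vertical <= config$stackVertical[2] + 1e-9 &&
          g$lateral <= config$stackLateral + 1e-9) {
        rows[[length(rows) + 1]] <- data.frame(
          nt = moieties[[b]]$key, partnerKind = kinds[p],
          partner = moieties[[p]]$partner,
          interplaneAngle = g$angle, verticalSep = g$vertical,
          lateralOffset = g$lateral, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$nt, out$partnerKind, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect pseudo base pairs
#'
#' A planar amino-acid group (guanidinium, Asn/Gln amide, Asp/Glu carboxyl,
#' His ring, aromatic ring) pseudo-pairs with a base when at least two
#' hydrogen bonds link the base moiety to the group's residue sidechain AND
#' the two planes are coplanar (acute angle at most \code{config$stackAngle})
#' AND nearly in-plane (vertical separation at most
#' \code{config$pairVertical}; larger separations are stacking, not pairing).
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @param config \code{contactConfig()} thresholds.
#' @param hbonds Optional precomputed \code{detectHBonds()} output.
#' @return data.frame with columns \code{nt}, \code{aa}, \code{nHBonds},
#'   \code{interplaneAngle}, \code{verticalSep}.
#' @export
detectPseudoPairs <- function(structure, config = contactConfig(),
                              hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- detectHBonds(structure, config)
  empty <- data.frame(nt = character(), aa = character(),
                      nHBonds = integer(), interplaneAngle = numeric(),
                      verticalSep = numeric(), stringsAsFactors = FALSE)
  hb <- hbonds[hbonds$rnaMoiety == "base" &
                 hbonds$proteinMoiety == "sidechain", , drop = FALSE]
  if (!nrow(hb)) return(empty)
  cnt <- table(paste(hb$nt, hb$aa, sep = "\r"))
  cand <- names(cnt)[cnt >= 2]
  if (!length(cand)) return(empty)
  res <- residueTable(structure)
  rows <- list()
  for (pr in cand) {
    parts <- strsplit(pr, "\r", fixed = TRUE)[[1]]
    nt <- parts[1]; aa <- parts[2]
    base <- res$canonical[res$key == nt][1]
    aa3 <- res$canonical[res$key == aa][1]
    ringAtoms <- .BASE_RING_ATOMS[[base]]
    planeAtoms <- .PSEUDOPAIR_PLANES[[aa3]]
    if (is.null(ringAtoms) || is.null(planeAtoms)) next
    p1 <- tryCatch(fitPlane(.atomXYZ(.residueAtoms(structure, nt), ringAtoms)),
                   error = function(e) NULL)
    xyz2 <- .atomXYZ(.residueAtoms(structure, aa), planeAtoms)
    p2 <- if (is.null(xyz2)) NULL else
      tryCatch(fitPlane(xyz2), error = function(e) NULL)
    if (is.null(p1) || is.null(p2)) next
    g <- .stackGeometry(p1, p2)
    if (g$angle <= config$stackAngle + 1e-9 &&
        g$vertical <= config$pairVertical + 1e-9) {
      rows[[length(rows) + 1]] <- data.frame(
        nt = nt, aa = aa, nHBonds = as.integer(cnt[pr]),
        interplaneAngle = g$angle, verticalSep = g$vertical,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$nt, out$aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
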