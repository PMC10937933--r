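#' @import methods
NULL

#' ComplexStructure: a parsed protein-RNA complex
#'
#' Uniform coordinate model for one model of a macromolecular complex:
#' a flat atom table (one row per heavy or hydrogen atom) plus a per-chain
#' polymer classification. Residues are addressed by author numbering
#' (\code{chain}, \code{resno}, \code{insert}), the coordinate system all
#' crosslink-site mapping uses.
#'
#' @slot accession Identifier (PDB code or fixture name).
#' @slot modelIndex Which model of a multi-model file was kept (1-based).
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety} (atom name), \code{elesy}
#'   (element), \code{x}, \code{y}, \code{z}, \code{o} (occupancy),
#'   \code{alt}, \code{hydrogen} (logical flag), \code{kind} (residue kind).
#' @slot chainClass Named character vector: chain id -> polymer class in
#'   \code{protein}, \code{RNA}, \code{DNA}, \code{other}.
#' @exportClass ComplexStructure
setClass("ComplexStructure",
  representation(
    accession = "character",
    modelIndex = "integer",
    atoms = "data.frame",
    chainClass = "character"
  )
)

setValidity("ComplexStructure", function(object) {
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "alt", "hydrogen", "kind")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss)) return(paste("atoms lacks columns:",
                                 paste(miss, collapse = ", ")))
  if (nrow(object@atoms) == 0) return("structure has no atoms")
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) return("non-finite coordinates")
  if (any(!nzchar(object@atoms$elesy))) return("empty element symbols")
  if (!all(unique(object@atoms$chain) %in% names(object@chainClass)))
    return("chainClass missing entries for some chains")
  TRUE
})

#' InterfaceAnnotation: per-structure interface annotation bundle
#'
#' Holds every interface annotation computed for one structure: heavy-atom
#' contacts, typed hydrogen bonds, planar stacking records, pseudo base
#' pairs, per-nucleotide sugar pucker and base orientation, and RNA pairing
#' context. Each slot is a data.frame (possibly empty) with fixed columns;
#' residues are referenced by \code{chain:resno:insert} keys.
#'
#' @slot accession Structure identifier the annotation belongs to.
#' @slot contacts ContactRecord rows: \code{nt}, \code{aa}, \code{ntBase},
#'   \code{aaName}, \code{minDistance}, \code{typedOnly} (kept above the
#'   generic cutoff because a typed interaction exists).
#' @slot hbonds HBond rows: donor/acceptor residue + atom, distance,
#'   \code{rnaMoiety}, \code{proteinMoiety}, plus \code{nt}, \code{aa} keys.
#' @slot stacks StackRecord rows: \code{nt}, \code{partnerKind},
#'   \code{partner}, \code{interplaneAngle}, \code{verticalSep},
#'   \code{lateralOffset}.
#' @slot pseudoPairs PseudoPair rows: \code{nt}, \code{aa}, \code{nHBonds},
#'   \code{interplaneAngle}, \code{verticalSep}.
#' @slot puckers SugarPucker rows: \code{nt}, \code{nu0}..\code{nu4},
#'   \code{P}, \code{tauM}, \code{puckerClass}, \code{family}.
#' @slot orientations BaseOrientation rows: \code{nt}, \code{chi},
#'   \code{orientation}.
#' @slot secondary NucSecondary rows: \code{nt}, \code{paired},
#'   \code{element}, \code{stacked5p}, \code{stacked3p}.
#' @exportClass InterfaceAnnotation
setClass("InterfaceAnnotation",
  representation(
    accession = "character",
    contacts = "data.frame",
    hbonds = "data.frame",
    stacks = "data.frame",
    pseudoPairs = "data.frame",
    puckers = "data.frame",
    orientations = "data.frame",
    secondary = "data.frame"
  )
)

#' @keywords internal
.resKey <- function(chain, resno, insert) {
  paste(chain, resno, ifelse(is.na(insert) | insert == "", ".", insert),
        sep = ":")
}

setMethod("show", "ComplexStructure", function(object) {
  cat("ComplexStructure", object@accession,
      sprintf("(model %d)\n", object@modelIndex))
  tab <- chainTable(object)
  cat(sprintf("  %d chains, %d atoms (%d hydrogens)\n",
              nrow(tab), nrow(object@atoms), sum(object@atoms$hydrogen)))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  chain %s: %-7s %d residues\n",
                tab$chain[i], tab$class[i], tab$nResidues[i]))
  invisible(NULL)
})

setMethod("show", "InterfaceAnnotation", function(object) {
  cat("InterfaceAnnotation for", object@accession, "\n")
  cat(sprintf("  %d contacts, %d H-bonds, %d stacks, %d pseudo pairs\n",
              nrow(object@contacts), nrow(object@hbonds),
              nrow(object@stacks), nrow(object@pseudoPairs)))
  cat(sprintf("  %d sugar puckers, %d base orientations, %d secondary rows\n",
              nrow(object@puckers), nrow(object@orientations),
              nrow(object@secondary)))
  invisible(NULL)
})

#' @describeIn ComplexStructure-class accession identifier
#' @param object A ComplexStructure or InterfaceAnnotation.
#' @export
accession <- function(object) object@accession

#' Atom table of a structure
#'
#' @param object A \linkS4class{ComplexStructure}.
#' @param heavyOnly Drop hydrogen/deuterium rows.
#' @return data.frame of atoms.
#' @export
atoms <- function(object, heavyOnly = FALSE) {
  at <- object@atoms
  if (heavyOnly) at <- at[!at$hydrogen, , drop = FALSE]
  at
}

#' Per-chain polymer classes
#' @param object A \linkS4class{ComplexStructure}.
#' @return Named character vector chain -> class.
#' @export
chainClasses <- function(object) object@chainClass

#' Chain summary table (id, polymer class, residue count)
#' @param object A \linkS4class{ComplexStructure}.
#' @return data.frame with columns \code{chain}, \code{class},
#'   \code{nResidues}.
#' @export
chainTable <- function(object) {
  at <- object@atoms
  key <- .resKey(at$chain, at$resno, at$insert)
  nres <- tapply(key, at$chain, function(k) length(unique(k)))
  chains <- unique(at$chain)
  data.frame(chain = chains,
             class = unname(object@chainClass[chains]),
             nResidues = as.integer(nres[chains]),
             stringsAsFactors = FALSE)
}

#' Residue table of a structure
#'
#' One row per residue in file order, with author numbering, canonical
#' residue name and kind.
#'
#' @param object A \linkS4class{ComplexStructure}.
#' @param kind Optional filter: keep residues of this kind only
#'   (e.g. \code{"ribonucleotide"}).
#' @return data.frame with columns \code{key}, \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{canonical}, \code{kind}.
#' @export
residueTable <- function(object, kind = NULL) {
  at <- object@atoms
  key <- .resKey(at$chain, at$resno, at$insert)
  first <- !duplicated(key)
  out <- data.frame(
    key = key[first],
    chain = at$chain[first],
    resno = at$resno[first],
    insert = at$insert[first],
    resid = at$resid[first],
    canonical = .canonicalResid(at$resid[first]),
    kind = at$kind[first],
    stringsAsFactors = FALSE
  )
  if (!is.null(kind)) out <- out[out$kind %in% kind, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
.residueAtoms <- function(object, key, heavyOnly = TRUE) {
  at <- object@atoms
  sel <- .resKey(at$chain, at$resno, at$insert) == key
  if (heavyOnly) sel <- sel & !at$hydrogen
  at[sel, , drop = FALSE]
}

#' @keywords internal
.atomXYZ <- function(at, names = NULL) {
  if (!is.null(names)) {
    idx <- match(names, at$elety)
    if (anyNA(idx)) return(NULL)
    at <- at[idx, , drop = FALSE]
  }
  as.matrix(at[, c("x", "y", "z")])
}
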