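## Ribose sugar pucker (pseudorotation) and glycosidic base orientation.

#' Sugar pucker of a ribonucleotide
#'
#' Computes the five endocyclic ribose torsions, the pseudorotation phase P
#' and amplitude tau_m, and bins P into the ten named pucker classes
#' (36-degree bins centered at 18 + k*36 degrees) and the N/S family
#' (N iff P in [270, 360) or [0, 90)).
#'
#' The torsions are nu0 = C4'-O4'-C1'-C2', nu1 = O4'-C1'-C2'-C3',
#' nu2 = C1'-C2'-C3'-C4', nu3 = C2'-C3'-C4'-O4', nu4 = C3'-C4'-O4'-C1';
#' tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72)), with P
#' shifted by 180 degrees when nu2 < 0, and tau_m = nu2 / cos P.
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @param nt Residue key (\code{chain:resno:insert}); see
#'   \code{\link{residueTable}}.
#' @return One-row data.frame: \code{nt}, \code{nu0}..\code{nu4}, \code{P}
#'   (degrees in [0, 360)), \code{tauM}, \code{puckerClass}, \code{family};
#'   or NULL with a warning when a ring atom is missing (the residue is then
#'   excluded from conformation features).
#' @export
sugarPucker <- function(structure, nt) {
  at <- .residueAtoms(structure, nt)
  if (!nrow(at)) stop("residue not found: ", nt)
  ring <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  xyz <- .atomXYZ(at, ring)
  if (is.null(xyz)) {
    warning("missing ribose ring atom(s) in ", nt,
            "; sugar pucker marked missing")
    return(NULL)
  }
  rownames(xyz) <- ring
  tor <- function(a, b, c, d) .dihedral(xyz[a, ], xyz[b, ], xyz[c, ], xyz[d, ])
  nu <- c(tor("C4'", "O4'", "C1'", "C2'"),
          tor("O4'", "C1'", "C2'", "C3'"),
          tor("C1'", "C2'", "C3'", "C4'"),
          tor("C2'", "C3'", "C4'", "O4'"),
          tor("C3'", "C4'", "O4'", "C1'"))
  ps <- .phaseFromNu(nu)
  data.frame(nt = nt, nu0 = nu[1], nu1 = nu[2], nu2 = nu[3], nu3 = nu[4],
             nu4 = nu[5], P = ps$P, tauM = ps$tauM,
             puckerClass = .puckerClass(ps$P),
             family = .puckerFamily(ps$P),
             stringsAsFactors = FALSE)
}

#' @keywords internal
.phaseFromNu <- function(nu) {
  denom <- 2 * nu[3] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  P <- atan2((nu[5] + nu[2]) - (nu[4] + nu[1]), denom) * 180 / pi
  ## atan2 already folds the nu2 < 0 sign into the quadrant, which is the
  ## same as the printed tan-then-shift rule
  P <- P %% 360
  tauM <- nu[3] / cos(P * pi / 180)
  list(P = P, tauM = tauM)
}

#' @keywords internal
.puckerClass <- function(P) .PUCKER_CLASSES[(floor((P %% 360) / 36) %% 10) + 1]

#' @keywords internal
.puckerFamily <- function(P) {
  P <- P %% 360
  ifelse(P < 90 | P >= 270, "N", "S")
}

#' Glycosidic base orientation (syn/anti)
#'
#' Computes the glycosidic torsion chi (O4'-C1'-N9-C4 for purines,
#' O4'-C1'-N1-C2 for pyrimidines), in (-180, 180]. The base is anti iff
#' |chi| >= 90 degrees, syn otherwise.
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @param nt Residue key.
#' @return One-row data.frame: \code{nt}, \code{chi}, \code{orientation};
#'   or NULL with a warning when chi atoms are missing.
#' @export
baseOrientation <- function(structure, nt) {
  at <- .residueAtoms(structure, nt)
  if (!nrow(at)) stop("residue not found: ", nt)
  base <- .canonicalResid(at$resid[1])
  names <- if (base %in% c("A", "G")) c("O4'", "C1'", "N9", "C4")
           else c("O4'", "C1'", "N1", "C2")
  xyz <- .atomXYZ(at, names)
  if (is.null(xyz)) {
    warning("missing chi atom(s) in ", nt, "; base orientation missing")
    return(NULL)
  }
  chi <- .dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  data.frame(nt = nt, chi = chi,
             orientation = if (abs(chi) >= 90) "anti" else "syn",
             stringsAsFactors = FALSE)
}
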