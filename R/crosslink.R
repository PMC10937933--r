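## Crosslink-site labeling from assay evidence.
##
## CLIP-derived instance tables (one row per transcriptome instance of an
## RNA ligand, with 0-based crosslink offsets) are turned into per-position
## crosslinked / non-crosslinked labels via pinned frequency thresholds;
## protein crosslink sites from RNA-interactome capture are mapped onto
## structure chains by sequence alignment.

#' Crosslink-calling thresholds
#'
#' A position is called crosslinked when at least
#' \code{minInstancesPrimary} instances carry crosslink evidence and the
#' per-position crosslinking frequency is at least \code{minFreqPrimary},
#' or, with fewer instances (at least \code{minInstancesFallback}), when
#' the frequency is at least \code{minFreqFallback}.
#'
#' @param minInstancesPrimary Default 20.
#' @param minFreqPrimary Default 0.3.
#' @param minInstancesFallback Default 10.
#' @param minFreqFallback Default 0.5.
#' @return Named list of thresholds.
#' @export
crosslinkCallConfig <- function(minInstancesPrimary = 20,
                                minFreqPrimary = 0.3,
                                minInstancesFallback = 10,
                                minFreqFallback = 0.5) {
  stopifnot(minFreqPrimary > 0, minFreqPrimary <= 1,
            minFreqFallback > 0, minFreqFallback <= 1,
            minInstancesFallback <= minInstancesPrimary)
  list(minInstancesPrimary = minInstancesPrimary,
       minFreqPrimary = minFreqPrimary,
       minInstancesFallback = minInstancesFallback,
       minFreqFallback = minFreqFallback)
}

#' Per-position crosslink counts and frequencies
#'
#' For a ligand instance table (list of per-instance 0-based crosslink
#' offset vectors), computes at each ligand position the number of
#' instances crosslinked there and the frequency. The denominator is the
#' number of instances carrying at least one crosslink call (instances
#' without evidence do not dilute the frequency); set
#' \code{denominator = "all"} for the all-instances variant.
#'
#' @param offsets List of integer vectors: 0-based crosslink offsets per
#'   instance (may be empty vectors).
#' @param ligandLength Length of the ligand (or searched subsequence).
#' @param denominator \code{"crosslinked"} (default) or \code{"all"}.
#' @return data.frame with columns \code{position} (0-based), \code{count},
#'   \code{frequency}; attribute \code{nInstances} is the denominator used.
#' @export
positionCrosslinkFrequency <- function(offsets, ligandLength,
                                       denominator = c("crosslinked",
                                                       "all")) {
  denominator <- match.arg(denominator)
  if (!length(offsets)) stop("empty instance table")
  for (i in seq_along(offsets)) {
    off <- offsets[[i]]
    if (length(off) && (any(off < 0) || any(off >= ligandLength)))
      stop("instance ", i, ": crosslink offset outside ligand (0-based, ",
           "length ", ligandLength, ")")
  }
  withXL <- vapply(offsets, function(o) length(o) > 0, logical(1))
  if (!any(withXL)) stop("no instance carries a crosslink call")
  nInst <- if (denominator == "crosslinked") sum(withXL) else length(offsets)
  counts <- integer(ligandLength)
  for (o in offsets) {
    p <- unique(o)  # one event per instance per position
    counts[p + 1L] <- counts[p + 1L] + 1L
  }
  out <- data.frame(position = seq_len(ligandLength) - 1L,
                    count = counts, frequency = counts / nInst)
  attr(out, "nInstances") <- nInst
  out
}

#' Call crosslinked positions from per-position frequencies
#'
#' Applies the two-branch threshold rule: crosslinked iff
#' (n >= minInstancesPrimary and f >= minFreqPrimary) or
#' (n >= minInstancesFallback and f >= minFreqFallback). Monotone in both
#' count and frequency.
#'
#' @param freqs Output of \code{\link{positionCrosslinkFrequency}}.
#' @param nInstances Number of instances with crosslink evidence; defaults
#'   to the attribute stored on \code{freqs}.
#' @param config \code{crosslinkCallConfig()} thresholds.
#' @return \code{freqs} with a \code{label} column
#'   (\code{"crosslinked"} / \code{"non-crosslinked"}).
#' @export
callCrosslinkedPositions <- function(freqs, nInstances = NULL,
                                     config = crosslinkCallConfig()) {
  if (is.null(nInstances)) nInstances <- attr(freqs, "nInstances")
  if (is.null(nInstances)) stop("nInstances not given and not an attribute")
  f <- freqs$frequency
  hit <- (nInstances >= config$minInstancesPrimary &
            f >= config$minFreqPrimary) |
         (nInstances >= config$minInstancesFallback &
            f >= config$minFreqFallback)
  freqs$label <- ifelse(hit, "crosslinked", "non-crosslinked")
  freqs
}

#' Read a ligand instance table from TSV
#'
#' Expected columns: \code{instance} (id) and \code{offsets} (comma-separated
#' 0-based crosslink positions, empty for instances without calls).
#'
#' @param path TSV path.
#' @return Named list of integer offset vectors.
#' @export
readInstanceTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("instance", "offsets") %in% names(tab)))
    stop("instance table needs columns 'instance' and 'offsets'")
  out <- lapply(tab$offsets, function(x) {
    x <- trimws(x)
    if (!nzchar(x)) integer(0)
    else as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  })
  names(out) <- tab$instance
  out
}

#' Map a protein crosslink site onto a structure chain
#'
#' RNA-interactome capture reports sites in full-protein numbering; chains
#' in deposited structures are often truncated or renumbered. The full
#' protein sequence is globally aligned to the chain's observed sequence
#' (match +1, mismatch -1, gap -2) and the site is carried through the
#' alignment; the mapping is accepted only when the aligned residue letter
#' matches and local identity around the site is at least
#' \code{minIdentity}.
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @param chain Protein chain id.
#' @param fullSequence Full protein sequence (one-letter string).
#' @param position 1-based site position in \code{fullSequence}.
#' @param aaLetter Expected amino acid at the site.
#' @param minIdentity Minimum alignment identity in the 21-residue window
#'   around the site (default 0.9).
#' @return List with \code{mapped} (logical), \code{key}, \code{resno},
#'   \code{reason} (when unmapped).
#' @export
mapProteinSiteToChain <- function(structure, chain, fullSequence, position,
                                  aaLetter, minIdentity = 0.9) {
  cls <- chainClasses(structure)
  if (is.na(cls[chain]) || cls[chain] != "protein")
    stop("chain ", chain, " is not a protein chain")
  res <- residueTable(structure, kind = "amino-acid")
  res <- res[res$chain == chain, , drop = FALSE]
  chainSeq <- paste(unname(.AA3[res$canonical]), collapse = "")
  if (substr(fullSequence, position, position) != aaLetter)
    return(list(mapped = FALSE, key = NA_character_, resno = NA_integer_,
                reason = "site letter does not match full sequence"))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(fullSequence), Biostrings::AAString(chainSeq),
    type = "global",
    substitutionMatrix = .unitSubstitutionMatrix(),
    gapOpening = 0, gapExtension = 2)
  p1 <- as.character(Biostrings::alignedPattern(aln))
  p2 <- as.character(Biostrings::alignedSubject(aln))
  a1 <- strsplit(p1, "")[[1]]
  a2 <- strsplit(p2, "")[[1]]
  ipos <- cumsum(a1 != "-")
  jpos <- cumsum(a2 != "-")
  col <- match(position, ifelse(a1 != "-", ipos, NA))
  if (is.na(col) || a2[col] == "-")
    return(list(mapped = FALSE, key = NA_character_, resno = NA_integer_,
                reason = "site falls in an alignment gap"))
  if (a2[col] != aaLetter)
    return(list(mapped = FALSE, key = NA_character_, resno = NA_integer_,
                reason = "aligned chain residue differs from site letter"))
  win <- max(1, col - 10):min(length(a1), col + 10)
  both <- a1[win] != "-" & a2[win] != "-"
  ident <- if (any(both)) mean(a1[win][both] == a2[win][both]) else 0
  if (ident < minIdentity)
    return(list(mapped = FALSE, key = NA_character_, resno = NA_integer_,
                reason = sprintf("local alignment identity %.2f < %.2f",
                                 ident, minIdentity)))
  j <- jpos[col]
  list(mapped = TRUE, key = res$key[j], resno = res$resno[j], reason = NA)
}

#' @keywords internal
.unitSubstitutionMatrix <- function() {
  letters <- c(.AA_LETTERS, "X")
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

#' Pick the representative structure among redundant candidates
#'
#' When several structures cover the same RNA-binding domain, the one with
#' the most crosslink evidence is kept; ties fall back to the number of
#' non-zero structural features, then to the lexicographically smallest
#' accession. Permutation-invariant over candidate order.
#'
#' @param candidates data.frame with columns \code{accession},
#'   \code{crosslinkCount}, \code{nonzeroFeatures}.
#' @return The chosen accession string.
#' @export
selectNonredundant <- function(candidates) {
  stopifnot(nrow(candidates) >= 1)
  ord <- order(-candidates$crosslinkCount, -candidates$nonzeroFeatures,
               candidates$accession)
  candidates$accession[ord[1]]
}

#' Split labeled residues by RNA contact and compare crosslink rates
#'
#' Divides amino acids into contacting / non-contacting groups and computes
#' the per-amino-acid crosslinking frequency in each group (crosslinked
#' residues of that amino acid divided by all residues of that amino acid
#' in the group), plus the contacting-over-non-contacting fold change.
#' Zero denominators yield NA frequencies (undefined, not zero).
#'
#' @param labels data.frame with columns \code{key}, \code{residue}
#'   (one-letter amino acid) and \code{label}
#'   (\code{"crosslinked"} / \code{"non-crosslinked"}).
#' @param contactingKeys Character vector of residue keys in direct RNA
#'   contact.
#' @return data.frame with one row per amino acid: counts and frequencies
#'   in both groups and \code{foldChange}.
#' @export
splitByContact <- function(labels, contactingKeys) {
  labels$contacting <- labels$key %in% contactingKeys
  aas <- sort(unique(labels$residue))
  rows <- lapply(aas, function(a) {
    sub <- labels[labels$residue == a, , drop = FALSE]
    fr <- function(grp) {
      g <- sub[sub$contacting == grp, , drop = FALSE]
      if (!nrow(g)) return(c(n = 0, xl = 0, freq = NA))
      c(n = nrow(g), xl = sum(g$label == "crosslinked"),
        freq = mean(g$label == "crosslinked"))
    }
    ct <- fr(TRUE); nc <- fr(FALSE)
    data.frame(residue = a,
               nContacting = ct["n"], xlContacting = ct["xl"],
               freqContacting = ct["freq"],
               nNonContacting = nc["n"], xlNonContacting = nc["xl"],
               freqNonContacting = nc["freq"],
               foldChange = ct["freq"] / nc["freq"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
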