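## One-call interface annotation bundling all geometry annotators.

#' Annotate a protein-RNA interface
#'
#' Runs the full annotation battery on one structure: heavy-atom contacts,
#' typed hydrogen bonds, planar stacking, pseudo base pairs, sugar pucker
#' and base orientation for every ribonucleotide, and RNA pairing context.
#'
#' Typed interactions occasionally sit slightly above the generic contact
#' cutoff; such residue pairs are retained in the contact table with
#' \code{typedOnly = TRUE} so the residues still count as contacting.
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @param config \code{contactConfig()} thresholds.
#' @return An \linkS4class{InterfaceAnnotation}.
#' @export
annotateInterface <- function(structure, config = contactConfig()) {
  contacts <- heavyAtomContacts(structure, config)
  contacts$typedOnly <- rep(FALSE, nrow(contacts))
  hbonds <- detectHBonds(structure, config)
  stacks <- detectStacking(structure, config)
  pseudo <- detectPseudoPairs(structure, config, hbonds = hbonds)

  ## retain typed pairs missing from the generic contact set
  typedPairs <- unique(rbind(
    if (nrow(hbonds)) hbonds[, c("nt", "aa")],
    if (nrow(pseudo)) pseudo[, c("nt", "aa")],
    if (nrow(stacks)) {
      aaStack <- stacks[stacks$partnerKind %in%
                          c("aromatic-sidechain", "guanidinium"), ,
                        drop = FALSE]
      if (nrow(aaStack))
        data.frame(nt = aaStack$nt, aa = aaStack$partner,
                   stringsAsFactors = FALSE)
    }))
  if (!is.null(typedPairs) && nrow(typedPairs)) {
    have <- paste(contacts$nt, contacts$aa, sep = "\r")
    miss <- typedPairs[!paste(typedPairs$nt, typedPairs$aa, sep = "\r") %in%
                         have, , drop = FALSE]
    if (nrow(miss)) {
      res <- residueTable(structure)
      extra <- do.call(rbind, lapply(seq_len(nrow(miss)), function(i) {
        a1 <- .residueAtoms(structure, miss$nt[i])
        a2 <- .residueAtoms(structure, miss$aa[i])
        d <- sqrt(min(.crossDist2(.atomXYZ(a1), .atomXYZ(a2))))
        data.frame(nt = miss$nt[i], aa = miss$aa[i],
                   ntBase = res$canonical[res$key == miss$nt[i]][1],
                   aaName = res$canonical[res$key == miss$aa[i]][1],
                   minDistance = d, typedOnly = TRUE,
                   stringsAsFactors = FALSE)
      }))
      contacts <- rbind(contacts, extra)
      contacts <- contacts[order(contacts$nt, contacts$aa), , drop = FALSE]
      rownames(contacts) <- NULL
    }
  }

  ntRes <- residueTable(structure, kind = "ribonucleotide")
  cls <- chainClasses(structure)
  ntRes <- ntRes[cls[ntRes$chain] == "RNA", , drop = FALSE]
  puckers <- do.call(rbind, lapply(ntRes$key, function(k)
    suppressWarnings(sugarPucker(structure, k))))
  orientations <- do.call(rbind, lapply(ntRes$key, function(k)
    suppressWarnings(baseOrientation(structure, k))))
  if (is.null(puckers))
    puckers <- data.frame(nt = character(), nu0 = numeric(), nu1 = numeric(),
                          nu2 = numeric(), nu3 = numeric(), nu4 = numeric(),
                          P = numeric(), tauM = numeric(),
                          puckerClass = character(), family = character(),
                          stringsAsFactors = FALSE)
  if (is.null(orientations))
    orientations <- data.frame(nt = character(), chi = numeric(),
                               orientation = character(),
                               stringsAsFactors = FALSE)

  new("InterfaceAnnotation",
      accession = structure@accession,
      contacts = contacts,
      hbonds = hbonds,
      stacks = stacks,
      pseudoPairs = pseudo,
      puckers = puckers,
      orientations = orientations,
      secondary = rnaPairingContext(structure, config))
}

#' Dump an interface annotation to TSV
#'
#' Writes one TSV per annotation kind (contacts, hbonds, stacks,
#' pseudo pairs, puckers, orientations, secondary) into a directory, or a
#' single JSON file when \code{format = "json"}.
#'
#' @param annotation An \linkS4class{InterfaceAnnotation}.
#' @param path Output directory (tsv) or file (json).
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
exportAnnotation <- function(annotation, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  slots <- c("contacts", "hbonds", "stacks", "pseudoPairs", "puckers",
             "orientations", "secondary")
  if (format == "json") {
    obj <- lapply(slots, function(s) slot(annotation, s))
    names(obj) <- slots
    jsonlite::write_json(obj, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (s in slots)
      utils::write.table(slot(annotation, s),
                         file.path(path, paste0(s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
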