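## Structure reading/writing and chain classification.
##
## PDB and mmCIF parsing is delegated to bio3d; this layer normalizes atom
## names, resolves alternate locations, flags hydrogens, assigns residue
## kinds and classifies polymer chains into protein/RNA/DNA/other.

#' Build a ComplexStructure from a raw atom table
#'
#' Normalizes atom names (\code{*} and \code{"} prime conventions to
#' \code{'}), resolves altloc duplicates to the highest-occupancy copy
#' (ties broken toward altloc \code{"A"}, then file order), flags
#' hydrogen/deuterium atoms, assigns residue kinds from the pinned residue
#' dictionary and classifies chains.
#'
#' @param atoms data.frame with at least \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{x}, \code{y}, \code{z}; optional
#'   \code{insert}, \code{alt}, \code{o}, \code{elesy}.
#' @param accession Identifier stored on the object.
#' @param modelIndex Model number the atoms came from.
#' @return A \linkS4class{ComplexStructure}.
#' @export
newComplexStructure <- function(atoms, accession = "structure",
                                modelIndex = 1L) {
  at <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(at$insert)) at$insert <- ""
  if (is.null(at$alt)) at$alt <- ""
  if (is.null(at$o)) at$o <- 1
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$chain <- as.character(at$chain)
  at$chain[is.na(at$chain) | at$chain == ""] <- " "
  at$resno <- as.integer(at$resno)
  at$elety <- gsub("[*\"]", "'", trimws(at$elety))
  at$resid <- toupper(trimws(at$resid))
  if (is.null(at$elesy) || all(is.na(at$elesy)) || all(!nzchar(at$elesy))) {
    at$elesy <- gsub("[^A-Za-z].*", "", gsub("^[0-9]*", "", at$elety))
    at$elesy <- toupper(substr(at$elesy, 1, 1))
  }
  at$elesy <- toupper(trimws(at$elesy))
  at$hydrogen <- at$elesy %in% c("H", "D")

  ## altloc resolution: per (chain, resno, insert, elety) keep the
  ## highest-occupancy copy; ties resolved toward altloc "A", then order.
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(akey)) {
    pref <- order(akey, -at$o, at$alt != "A", seq_len(nrow(at)))
    at <- at[pref, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "\r")), , drop = FALSE]
    at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "\r"),
                         unique(paste(at$chain, at$resno, at$insert,
                                      sep = "\r")))), , drop = FALSE]
  }
  rownames(at) <- NULL

  at$kind <- .assignKinds(at)
  obj <- new("ComplexStructure",
             accession = accession,
             modelIndex = as.integer(modelIndex),
             atoms = at,
             chainClass = .classifyChainVector(at))
  validObject(obj)
  obj
}

## Residue kind assignment: dictionary lookup, with O2' presence used to
## separate ribo- from deoxynucleotides for bare A/C/G/U-named residues.
#' @keywords internal
.assignKinds <- function(at) {
  key <- .resKey(at$chain, at$resno, at$insert)
  kind <- .residueKind(at$resid)
  ribo <- which(kind == "ribonucleotide")
  if (length(ribo)) {
    hasO2p <- tapply(at$elety == "O2'", key, any)
    ## only demote when a real sugar ring is modeled (C3' and C4' present);
    ## base-only fixtures with a lone C1' stay ribonucleotides
    hasSugar <- tapply(at$elety == "C3'", key, any) &
      tapply(at$elety == "C4'", key, any)
    demote <- key %in% names(hasO2p)[!hasO2p & hasSugar]
    kind[ribo[demote[ribo]]] <- "deoxynucleotide"
  }
  kind
}

#' @keywords internal
.classifyChainVector <- function(at) {
  chains <- unique(at$chain)
  out <- vapply(chains, function(ch) {
    sub <- at[at$chain == ch, , drop = FALSE]
    key <- .resKey(sub$chain, sub$resno, sub$insert)
    kinds <- sub$kind[!duplicated(key)]
    poly <- kinds[kinds != "other"]
    if (!length(poly)) return("other")
    tab <- table(poly)
    top <- names(tab)[which.max(tab)]
    switch(top,
           "amino-acid" = "protein",
           "ribonucleotide" = "RNA",
           "deoxynucleotide" = "DNA",
           "other")
  }, character(1))
  names(out) <- chains
  out
}

#' Classify polymer chains of a structure
#'
#' A chain is RNA if the majority of its polymer residues are
#' ribonucleotides (O2' presence separates ribo from deoxy), protein if the
#' majority are amino acids, DNA for deoxynucleotide chains, and other for
#' chains of only ligands, ions or waters. Deterministic and invariant to
#' residue order.
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @return Named character vector chain id -> polymer class.
#' @export
classifyChains <- function(structure) .classifyChainVector(structure@atoms)

#' Read a protein-RNA complex structure
#'
#' Reads PDB or mmCIF through bio3d, keeps the first model by default,
#' resolves altlocs to the highest-occupancy copy, and retains hydrogens
#' (flagged, excluded from all distance computations downstream).
#'
#' @param path File path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @param model Model index to keep from multi-model files (default 1).
#' @param accession Identifier to store; defaults to the file stem.
#' @return A \linkS4class{ComplexStructure}. Structures lacking a protein
#'   or an RNA chain are readable; a warning flags them.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          model = 1L, accession = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (is.null(accession))
    accession <- tools::file_path_sans_ext(basename(path))
  raw <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- raw$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at <- at[!(toupper(at$resid) %in% c("HOH", "DOD", "WAT")) |
             rep(TRUE, nrow(at)), , drop = FALSE]  # waters kept; class other
  str <- newComplexStructure(
    data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
               resid = at$resid, elety = at$elety, elesy = at$elesy,
               x = at$x, y = at$y, z = at$z, o = at$o, alt = at$alt,
               stringsAsFactors = FALSE),
    accession = accession, modelIndex = as.integer(model))
  cls <- chainClasses(str)
  if (!any(cls == "protein") || !any(cls == "RNA"))
    warning("structure ", accession,
            " lacks a protein or RNA chain (classes: ",
            paste(unique(cls), collapse = ", "), ")")
  str
}

#' Write a structure to PDB or mmCIF
#'
#' PDB emission goes through bio3d; mmCIF emission writes a minimal
#' \code{atom_site} loop. Files written here round-trip through
#' \code{readStructure} with coordinates equal to PDB field precision
#' (1e-3 Angstrom).
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @param path Output file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(structure, path,
                           format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  at <- structure@atoms
  if (format == "pdb") {
    bio3d::write.pdb(pdb = NULL, file = path,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(at)),
                     resno = at$resno, resid = at$resid,
                     eleno = seq_len(nrow(at)), elety = at$elety,
                     chain = ifelse(at$chain == " ", "", at$chain),
                     insert = at$insert, alt = at$alt,
                     o = at$o, b = rep(0, nrow(at)), elesy = at$elesy)
  } else {
    ## standard RCSB atom_site field order
    lines <- c(
      paste0("data_", gsub("[^A-Za-z0-9_-]", "_", structure@accession)),
      "#", "loop_",
      paste0("_atom_site.", c(
        "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
        "label_comp_id", "label_asym_id", "label_entity_id",
        "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
        "Cartn_z", "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
        "auth_seq_id", "auth_comp_id", "auth_asym_id", "auth_atom_id",
        "pdbx_PDB_model_num")),
      sprintf(paste("ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f",
                    "%.2f 0.00 ? %d %s %s %s %d"),
              seq_len(nrow(at)), at$elesy, at$elety,
              ifelse(at$alt == "", ".", at$alt), at$resid,
              ifelse(at$chain == " ", "A", at$chain), at$resno,
              ifelse(at$insert == "", "?", at$insert),
              at$x, at$y, at$z, at$o, at$resno, at$resid,
              ifelse(at$chain == " ", "A", at$chain), at$elety,
              structure@modelIndex),
      "#")
    writeLines(lines, path)
  }
  invisible(path)
}
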