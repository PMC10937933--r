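## Tabulation of interface annotations into the fixed feature schemas.

## Per-amino-acid typed-interaction tallies for one nucleotide, by contact
## class. Peptide-bond stacks credit both residues of the dipeptide.
#' @keywords internal
.ntClassCounts <- function(annotation, nt, res) {
  counts <- matrix(0, nrow = length(.CONTACT_CLASSES),
                   ncol = length(.AA_LETTERS),
                   dimnames = list(.CONTACT_CLASSES, .AA_LETTERS))
  bump <- function(class, aaKeys) {
    aa3 <- res$canonical[match(aaKeys, res$key)]
    aa1 <- .AA3[aa3]
    for (l in aa1[!is.na(aa1)]) counts[class, l] <<- counts[class, l] + 1
  }
  st <- annotation@stacks
  st <- st[st$nt == nt & st$partnerKind != "nucleotide-base", , drop = FALSE]
  for (i in seq_len(nrow(st))) {
    if (st$partnerKind[i] == "peptide-bond")
      bump("stack", strsplit(st$partner[i], "+", fixed = TRUE)[[1]])
    else bump("stack", st$partner[i])
  }
  pp <- annotation@pseudoPairs
  pp <- pp[pp$nt == nt, , drop = FALSE]
  if (nrow(pp)) bump("pseudopair", pp$aa)
  hb <- annotation@hbonds
  hb <- hb[hb$nt == nt, , drop = FALSE]
  if (nrow(hb)) {
    cls <- paste("hb", hb$rnaMoiety, hb$proteinMoiety, sep = "_")
    for (i in seq_len(nrow(hb))) bump(cls[i], hb$aa[i])
  }
  counts
}

#' Tabulate the 246 nucleotide features
#'
#' Fills the pinned \code{\link{nucleotideSchema}} for one nucleotide from
#' an interface annotation. Count features are per-amino-acid tallies of
#' typed interactions, with category aggregates summed over member amino
#' acids; conformation, secondary-structure and pairing blocks are one-hot;
#' missing annotations leave their one-hot group all zero.
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @param annotation Matching \linkS4class{InterfaceAnnotation}.
#' @param nt Residue key of a ribonucleotide in the structure.
#' @return Named numeric vector of length 246 in schema order.
#' @export
buildNucleotideFeatures <- function(structure, annotation, nt) {
  res <- residueTable(structure)
  if (!nt %in% res$key) stop("nucleotide not in structure: ", nt)
  schema <- nucleotideSchema()
  v <- stats::setNames(numeric(nrow(schema)), schema$name)

  counts <- .ntClassCounts(annotation, nt, res)
  catMap <- aaCategoryMap()
  for (cc in .CONTACT_CLASSES) {
    v[paste(cc, .AA_LETTERS, sep = ".")] <- counts[cc, ]
    for (cat in .AA_CATEGORIES)
      v[paste(cc, "cat", cat, sep = ".")] <- sum(counts[cc, catMap[[cat]]])
    v[paste0("total.", cc)] <- sum(counts[cc, ])
  }

  pk <- annotation@puckers
  pk <- pk[pk$nt == nt, , drop = FALSE]
  if (nrow(pk)) {
    v[paste0("pucker.", .sanitizeName(pk$puckerClass[1]))] <- 1
    v[paste0("pucker.family.", pk$family[1])] <- 1
  }
  ori <- annotation@orientations
  ori <- ori[ori$nt == nt, , drop = FALSE]
  if (nrow(ori)) v[paste0("orient.", ori$orientation[1])] <- 1
  ss <- annotation@secondary
  ss <- ss[ss$nt == nt, , drop = FALSE]
  if (nrow(ss)) {
    v[paste0("ss.", .sanitizeName(ss$element[1]))] <- 1
    v[if (ss$paired[1]) "paired.yes" else "paired.no"] <- 1
    v["neighbor.stack5p"] <- as.numeric(ss$stacked5p[1])
    v["neighbor.stack3p"] <- as.numeric(ss$stacked3p[1])
  }

  ct <- annotation@contacts
  ct <- ct[ct$nt == nt, , drop = FALSE]
  v["n_contacting_residues"] <- length(unique(ct$aa))
  v["n_hbonds_total"] <- sum(annotation@hbonds$nt == nt)
  v["n_typed_interactions_total"] <-
    sum(annotation@hbonds$nt == nt) +
    sum(annotation@stacks$nt == nt &
          annotation@stacks$partnerKind != "nucleotide-base") +
    sum(annotation@pseudoPairs$nt == nt)
  v["min_contact_distance"] <- if (nrow(ct)) min(ct$minDistance) else 0
  v
}

#' Tabulate the 36 amino-acid features
#'
#' Fills the pinned \code{\link{aaSchema}} for one amino acid: hydrogen
#' bonds typed by base x RNA moiety x protein moiety, stacking and
#' pseudo-pair counts per base, and summary totals. Peptide-bond stacks
#' credit both residues of the dipeptide.
#'
#' @inheritParams buildNucleotideFeatures
#' @param aa Residue key of an amino acid in the structure.
#' @return Named numeric vector of length 36 in schema order.
#' @export
buildAAFeatures <- function(structure, annotation, aa) {
  res <- residueTable(structure)
  if (!aa %in% res$key) stop("amino acid not in structure: ", aa)
  schema <- aaSchema()
  v <- stats::setNames(numeric(nrow(schema)), schema$name)

  hb <- annotation@hbonds
  hb <- hb[hb$aa == aa & hb$ntBase %in% c("A", "C", "G", "U"), , drop = FALSE]
  if (nrow(hb)) {
    nm <- paste("hb", hb$ntBase, hb$rnaMoiety, hb$proteinMoiety, sep = ".")
    for (x in nm) v[x] <- v[x] + 1
  }
  st <- annotation@stacks
  st <- st[st$partnerKind != "nucleotide-base", , drop = FALSE]
  mine <- vapply(seq_len(nrow(st)), function(i) {
    if (st$partnerKind[i] == "peptide-bond")
      aa %in% strsplit(st$partner[i], "+", fixed = TRUE)[[1]]
    else st$partner[i] == aa
  }, logical(1))
  st <- st[mine, , drop = FALSE]
  if (nrow(st)) {
    base <- res$canonical[match(st$nt, res$key)]
    for (b in base[base %in% c("A", "C", "G", "U")])
      v[paste0("stack.", b)] <- v[paste0("stack.", b)] + 1
  }
  pp <- annotation@pseudoPairs
  pp <- pp[pp$aa == aa, , drop = FALSE]
  if (nrow(pp)) {
    base <- res$canonical[match(pp$nt, res$key)]
    for (b in base[base %in% c("A", "C", "G", "U")])
      v[paste0("pseudopair.", b)] <- v[paste0("pseudopair.", b)] + 1
  }
  v["total_hbonds"] <- nrow(hb)
  v["total_stacks"] <- nrow(st)
  v["total_pseudopairs"] <- nrow(pp)
  ct <- annotation@contacts
  v["n_contacted_nucleotides"] <- length(unique(ct$nt[ct$aa == aa]))
  v
}

#' Feature table for all nucleotides or amino acids of a structure
#'
#' Builds one row per residue (all RNA ribonucleotides, or all amino acids
#' of protein chains) with metadata columns followed by the schema columns.
#'
#' @param structure A \linkS4class{ComplexStructure}.
#' @param annotation Optional precomputed annotation (computed if NULL).
#' @param task \code{"nucleotide"} or \code{"amino-acid"}.
#' @param contactingOnly Keep only residues with at least one cross-polymer
#'   contact (the classification sets downstream use contacting residues
#'   only).
#' @param config \code{contactConfig()} thresholds.
#' @return data.frame: metadata (\code{accession}, \code{key}, \code{chain},
#'   \code{resno}, \code{insert}, \code{residue}) then the schema columns.
#' @export
featurizeStructure <- function(structure, annotation = NULL,
                               task = c("nucleotide", "amino-acid"),
                               contactingOnly = FALSE,
                               config = contactConfig()) {
  task <- match.arg(task)
  if (is.null(annotation)) annotation <- annotateInterface(structure, config)
  cls <- chainClasses(structure)
  if (task == "nucleotide") {
    res <- residueTable(structure, kind = "ribonucleotide")
    res <- res[cls[res$chain] == "RNA", , drop = FALSE]
    contacting <- unique(annotation@contacts$nt)
    build <- function(k) buildNucleotideFeatures(structure, annotation, k)
  } else {
    res <- residueTable(structure, kind = "amino-acid")
    res <- res[cls[res$chain] == "protein", , drop = FALSE]
    contacting <- unique(annotation@contacts$aa)
    build <- function(k) buildAAFeatures(structure, annotation, k)
  }
  if (contactingOnly) res <- res[res$key %in% contacting, , drop = FALSE]
  feats <- do.call(rbind, lapply(res$key, build))
  meta <- data.frame(accession = structure@accession, key = res$key,
                     chain = res$chain, resno = res$resno,
                     insert = res$insert,
                     residue = if (task == "nucleotide") res$canonical
                               else unname(.AA3[res$canonical]),
                     stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(feats))
  rownames(out) <- NULL
  attr(out, "task") <- task
  attr(out, "version") <- .SCHEMA_VERSION
  out
}

#' Append identity one-hot blocks to a feature table
#'
#' For nucleotide tables: base one-hot (4), overlapping left and right
#' dinucleotide one-hots (16 + 16); terminal positions get all-zero
#' dinucleotide blocks. For amino-acid tables: amino-acid one-hot (20) plus
#' preceding/following dipeptide one-hots expanded only over pairs observed
#' in the table (avoiding 400-wide constant-zero blocks).
#'
#' Sequence context comes from residue order along each chain of the source
#' structures, so the tables must retain their metadata columns.
#'
#' @param table Output of \code{\link{featurizeStructure}} (possibly
#'   row-filtered), or any data.frame with the same metadata columns.
#' @param structures Named list of \linkS4class{ComplexStructure} objects,
#'   names matching \code{table$accession}.
#' @return The table with identity columns appended.
#' @export
encodeIdentities <- function(table, structures) {
  task <- attr(table, "task")
  if (is.null(task))
    task <- if ("residue" %in% names(table) &&
                all(table$residue %in% c("A", "C", "G", "U")))
      "nucleotide" else "amino-acid"
  if (inherits(structures, "ComplexStructure"))
    structures <- stats::setNames(list(structures), structures@accession)

  ## neighbor letters from chain order in the source structure
  neigh <- function(i, offset) {
    s <- structures[[table$accession[i]]]
    if (is.null(s)) return(NA_character_)
    kind <- if (task == "nucleotide") "ribonucleotide" else "amino-acid"
    res <- residueTable(s, kind = kind)
    res <- res[res$chain == table$chain[i], , drop = FALSE]
    at <- match(table$key[i], res$key)
    j <- at + offset
    if (is.na(at) || j < 1 || j > nrow(res)) return(NA_character_)
    if (task == "nucleotide") res$canonical[j] else unname(.AA3[res$canonical[j]])
  }
  n <- nrow(table)
  prev <- vapply(seq_len(n), neigh, "", offset = -1L)
  nxt <- vapply(seq_len(n), neigh, "", offset = +1L)

  oneHot <- function(x, levels, prefix) {
    m <- matrix(0, n, length(levels),
                dimnames = list(NULL, paste(prefix, levels, sep = ".")))
    hit <- match(x, levels)
    ok <- !is.na(hit)
    m[cbind(which(ok), hit[ok])] <- 1
    as.data.frame(m)
  }

  if (task == "nucleotide") {
    bases <- c("A", "C", "G", "U")
    dinucs <- as.vector(outer(bases, bases, paste0))
    blocks <- cbind(
      oneHot(table$residue, bases, "id.base"),
      oneHot(paste0(prev, table$residue), dinucs, "id.left"),
      oneHot(paste0(table$residue, nxt), dinucs, "id.right"))
  } else {
    pre <- paste0(prev, table$residue)
    post <- paste0(table$residue, nxt)
    pre[is.na(prev)] <- NA
    post[is.na(nxt)] <- NA
    blocks <- cbind(
      oneHot(table$residue, .AA_LETTERS, "id.aa"),
      oneHot(pre, sort(unique(stats::na.omit(pre))), "id.pre"),
      oneHot(post, sort(unique(stats::na.omit(post))), "id.post"))
  }
  out <- cbind(table, blocks)
  attr(out, "task") <- task
  attr(out, "version") <- attr(table, "version")
  out
}

.META_COLS <- c("accession", "key", "chain", "resno", "insert", "residue")

#' Write a feature table as self-describing TSV
#'
#' The header carries the schema version and per-column group labels as
#' \code{#}-prefixed lines; \code{\link{importFeatureTable}} validates
#' column count and order against them.
#'
#' @param table Output of \code{\link{featurizeStructure}} (optionally with
#'   identity blocks and a \code{label} column).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
exportFeatureTable <- function(table, path) {
  version <- attr(table, "version")
  if (is.null(version)) version <- .SCHEMA_VERSION
  task <- attr(table, "task")
  if (is.null(task)) task <- "nucleotide"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# xlink3d feature table; schema ", version, "; task ", task),
    paste0("# columns: ", paste(names(table), collapse = "\t"))), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a feature table written by exportFeatureTable
#'
#' @param path TSV path.
#' @return data.frame with \code{task} and \code{version} attributes.
#' @export
importFeatureTable <- function(path) {
  header <- readLines(path, n = 2)
  if (length(header) < 2 || !grepl("^# xlink3d feature table", header[1]))
    stop("not an xlink3d feature table (missing header): ", path)
  version <- sub("^.*schema ([^;]+);.*$", "\\1", header[1])
  task <- sub("^.*task (.*)$", "\\1", header[1])
  declared <- strsplit(sub("^# columns: ", "", header[2]), "\t")[[1]]
  out <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e)
      stop("feature table body does not match its declared columns: ",
           conditionMessage(e)))
  if (!identical(names(out), declared)) {
    if (length(names(out)) != length(declared))
      stop("feature table has ", length(names(out)), " columns, header ",
           "declares ", length(declared), " (schema ", version, ")")
    bad <- which(names(out) != declared)[1]
    stop("feature table column mismatch at position ", bad, ": got '",
         names(out)[bad], "', header declares '", declared[bad],
         "' (schema ", version, ")")
  }
  attr(out, "task") <- task
  attr(out, "version") <- version
  out
}
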