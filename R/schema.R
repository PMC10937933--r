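## Pinned feature schemas.
##
## The nucleotide schema (v1) has exactly 246 columns in 15 groups; the
## amino-acid schema exactly 36 columns. The layout is reconstructed from
## the named feature kinds (typed hydrogen bonds incl. phosphate x
## sidechain, stacking, pseudo pairing, sugar pucker, base orientation,
## secondary structure, category aggregates) so the group and column totals
## match the published schema sizes.

.SCHEMA_VERSION <- "v1"

.AA_LETTERS <- sort(unname(.AA3))  # 20 one-letter codes, alphabetical
.AA_CATEGORIES <- c("polar", "positive", "negative", "hydrophobic",
                    "aromatic", "aliphatic")

## the eight typed-contact classes, in pinned order
.CONTACT_CLASSES <- c("stack", "pseudopair",
                      "hb_base_sidechain", "hb_base_backbone",
                      "hb_sugar_sidechain", "hb_sugar_backbone",
                      "hb_phosphate_sidechain", "hb_phosphate_backbone")

#' @keywords internal
.sanitizeName <- function(x) gsub("'", "p", gsub("-", "_", x))

#' The pinned 246-column nucleotide feature schema
#'
#' Groups 1-8: the eight typed-contact classes x (20 amino acids + 6
#' category aggregates) = 208 count features. Group 9: sugar-pucker class
#' one-hot (10) + N/S family one-hot (2). Group 10: base orientation
#' one-hot (2). Group 11: secondary-element one-hot (8). Group 12: pairing
#' status one-hot (2). Group 13: 5'/3' neighbor base-stacking flags (2).
#' Group 14: per-contact-class totals (8). Group 15: interface summary (4).
#'
#' @return data.frame with columns \code{name} and \code{group}
#'   (246 rows, 15 distinct groups), attribute \code{version}.
#' @examples
#' nrow(nucleotideSchema())
#' @export
nucleotideSchema <- function() {
  rows <- list()
  for (cc in .CONTACT_CLASSES) {
    rows[[length(rows) + 1]] <- data.frame(
      name = c(paste(cc, .AA_LETTERS, sep = "."),
               paste(cc, "cat", .AA_CATEGORIES, sep = ".")),
      group = cc, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(
    name = c(paste0("pucker.", .sanitizeName(.PUCKER_CLASSES)),
             "pucker.family.N", "pucker.family.S"),
    group = "sugar_pucker", stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    name = c("orient.anti", "orient.syn"),
    group = "base_orientation", stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    name = paste0("ss.", .sanitizeName(.SS_ELEMENTS)),
    group = "secondary_element", stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    name = c("paired.yes", "paired.no"),
    group = "pairing_status", stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    name = c("neighbor.stack5p", "neighbor.stack3p"),
    group = "neighbor_stacking", stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    name = paste0("total.", .CONTACT_CLASSES),
    group = "contact_totals", stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    name = c("n_contacting_residues", "n_hbonds_total",
             "n_typed_interactions_total", "min_contact_distance"),
    group = "interface_summary", stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(nrow(out) == 246, length(unique(out$group)) == 15,
            !anyDuplicated(out$name))
  attr(out, "version") <- .SCHEMA_VERSION
  out
}

#' The pinned 36-column amino-acid feature schema
#'
#' Hydrogen-bond counts typed by base (A, C, G, U) x RNA moiety (base,
#' sugar, phosphate) x protein moiety (sidechain, backbone) = 24; stacking
#' counts per base (4); pseudo-pair counts per base (4); summary features
#' (total H-bonds, total stacks, total pseudo pairs, number of contacted
#' nucleotides; 4).
#'
#' @return data.frame with columns \code{name} and \code{group} (36 rows),
#'   attribute \code{version}.
#' @examples
#' nrow(aaSchema())
#' @export
aaSchema <- function() {
  grid <- expand.grid(pm = c("sidechain", "backbone"),
                      rm = c("base", "sugar", "phosphate"),
                      base = c("A", "C", "G", "U"),
                      stringsAsFactors = FALSE)
  out <- rbind(
    data.frame(name = paste("hb", grid$base, grid$rm, grid$pm, sep = "."),
               group = "hbond", stringsAsFactors = FALSE),
    data.frame(name = paste0("stack.", c("A", "C", "G", "U")),
               group = "stacking", stringsAsFactors = FALSE),
    data.frame(name = paste0("pseudopair.", c("A", "C", "G", "U")),
               group = "pseudopair", stringsAsFactors = FALSE),
    data.frame(name = c("total_hbonds", "total_stacks", "total_pseudopairs",
                        "n_contacted_nucleotides"),
               group = "summary", stringsAsFactors = FALSE))
  rownames(out) <- NULL
  stopifnot(nrow(out) == 36, !anyDuplicated(out$name))
  attr(out, "version") <- .SCHEMA_VERSION
  out
}
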