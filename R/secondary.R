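## RNA pairing context from 3D coordinates: base pairs called by multiple
## base-base hydrogen bonds plus coplanarity, then a nested-pair analysis
## assigning loop elements, plus 5'/3' neighbor base-stacking flags.

#' Per-nucleotide RNA pairing context
#'
#' Calls base pairs (two bases joined by at least two base-base hydrogen
#' bonds with coplanar rings, acute interplane angle at most
#' \code{config$stackAngle}), then assigns each nucleotide a secondary
#' element: \code{helix-internal} or \code{helix-end} for paired
#' nucleotides; \code{hairpin-loop}, \code{internal-loop}, \code{bulge} or
#' \code{junction} for unpaired nucleotides enclosed by pairs;
#' \code{terminal-ss} for unpaired chain ends next to a helix; and
#' \code{isolated-ss} for nucleotides of chains with no pairs at all.
#' 5'/3' neighbor base-stacking flags come from \code{detectStacking}
#' restricted to nucleotide-base partners.
#'
#' @param structure A \linkS4class{ComplexStructure} with RNA chain(s).
#' @param config \code{contactConfig()} thresholds.
#' @return data.frame with columns \code{nt}, \code{paired},
#'   \code{partner}, \code{element}, \code{stacked5p}, \code{stacked3p}.
#' @export
rnaPairingContext <- function(structure, config = contactConfig()) {
  res <- residueTable(structure, kind = "ribonucleotide")
  cls <- chainClasses(structure)
  res <- res[cls[res$chain] == "RNA", , drop = FALSE]
  if (!nrow(res))
    return(data.frame(nt = character(), paired = logical(),
                      partner = character(), element = character(),
                      stacked5p = logical(), stacked3p = logical(),
                      stringsAsFactors = FALSE))
  n <- nrow(res)
  idx <- stats::setNames(seq_len(n), res$key)

  ## pair calling
  bb <- .baseBaseHBonds(structure, cutoff = config$hbCutoff)
  partner <- rep(NA_integer_, n)
  if (nrow(bb)) {
    pk <- paste(pmin(bb$nt1, bb$nt2), pmax(bb$nt1, bb$nt2), sep = "\r")
    cnt <- table(pk)
    cand <- names(cnt)[cnt >= 2]
    scored <- list()
    for (pr in cand) {
      parts <- strsplit(pr, "\r", fixed = TRUE)[[1]]
      k1 <- parts[1]; k2 <- parts[2]
      if (is.na(idx[k1]) || is.na(idx[k2])) next
      b1 <- res$canonical[idx[k1]]; b2 <- res$canonical[idx[k2]]
      p1 <- tryCatch(fitPlane(.atomXYZ(.residueAtoms(structure, k1),
                                       .BASE_RING_ATOMS[[b1]])),
                     error = function(e) NULL)
      p2 <- tryCatch(fitPlane(.atomXYZ(.residueAtoms(structure, k2),
                                       .BASE_RING_ATOMS[[b2]])),
                     error = function(e) NULL)
      if (is.null(p1) || is.null(p2)) next
      if (.interplaneAngle(p1$normal, p2$normal) > config$stackAngle + 1e-9)
        next
      scored[[length(scored) + 1]] <- list(i = idx[[k1]], j = idx[[k2]],
                                           nhb = as.integer(cnt[pr]))
    }
    if (length(scored)) {
      ## greedy assignment: most hydrogen bonds first, one partner per base
      ord <- order(-vapply(scored, `[[`, 0L, "nhb"))
      for (s in scored[ord]) {
        if (is.na(partner[s$i]) && is.na(partner[s$j])) {
          partner[s$i] <- s$j
          partner[s$j] <- s$i
        }
      }
    }
  }

  element <- rep(NA_character_, n)
  paired <- !is.na(partner)

  ## paired: helix-internal when the helix continues on both sides
  for (i in which(paired)) {
    j <- partner[i]
    contLeft <- i > 1 && !is.na(partner[i - 1]) && partner[i - 1] == j + 1
    contRight <- i < n && !is.na(partner[i + 1]) && partner[i + 1] == j - 1
    element[i] <- if (contLeft && contRight) "helix-internal" else "helix-end"
  }

  ## unpaired: classify runs chain by chain
  for (ch in unique(res$chain)) {
    pos <- which(res$chain == ch)
    chPaired <- paired[pos]
    if (!any(chPaired)) {
      element[pos] <- "isolated-ss"
      next
    }
    runs <- rle(!chPaired)
    at <- 1L
    for (r in seq_along(runs$lengths)) {
      len <- runs$lengths[r]
      if (runs$values[r]) {
        span <- pos[at:(at + len - 1)]
        leftIn <- at > 1L
        rightIn <- (at + len - 1L) < length(pos)
        if (!leftIn || !rightIn) {
          element[span] <- "terminal-ss"
        } else {
          a <- pos[at - 1L]          # paired neighbor on the 5' side
          b <- pos[at + len]         # paired neighbor on the 3' side
          pa <- partner[a]; pb <- partner[b]
          if (pa == b) {
            element[span] <- "hairpin-loop"
          } else if (pa == pb + 1L) {
            element[span] <- "bulge"
          } else if (pa > pb + 1L &&
                     all(!paired[seq(pb + 1L, pa - 1L)])) {
            element[span] <- "internal-loop"
          } else {
            element[span] <- "junction"
          }
        }
      }
      at <- at + len
    }
  }

  ## 5'/3' neighbor base-stacking flags
  st <- detectStacking(structure, config, partners = "nucleotide-base")
  stacked5p <- rep(FALSE, n)
  stacked3p <- rep(FALSE, n)
  if (nrow(st)) {
    for (r in seq_len(nrow(st))) {
      i <- idx[st$nt[r]]; j <- idx[st$partner[r]]
      if (is.na(i) || is.na(j)) next
      if (res$chain[i] == res$chain[j]) {
        if (j == i - 1) stacked5p[i] <- TRUE
        if (j == i + 1) stacked3p[i] <- TRUE
      }
    }
  }

  data.frame(nt = res$key, paired = paired,
             partner = ifelse(paired, res$key[partner], NA_character_),
             element = element, stacked5p = stacked5p,
             stacked3p = stacked3p, stringsAsFactors = FALSE)
}
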