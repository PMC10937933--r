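## Descriptive group comparisons and alignment-column projection.

#' Chi-squared composition test
#'
#' Pearson chi-squared test (no continuity correction) comparing categorical
#' compositions between groups, e.g. base composition of crosslinked vs
#' non-crosslinked nucleotides.
#'
#' @param table Contingency matrix (groups x categories), or two vectors of
#'   categorical outcomes via \code{...}.
#' @return List: \code{statistic}, \code{df}, \code{p}.
#' @export
compositionTest <- function(table) {
  table <- as.matrix(table)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test computed by full hypergeometric enumeration: with
#' margins fixed, the two-sided p-value is the sum of the probabilities of
#' all tables no more probable than the observed one (the standard
#' convention, with a small relative tolerance when comparing
#' probabilities). The returned odds ratio is the sample (cross-product)
#' odds ratio.
#'
#' @param table 2x2 integer matrix with positive margins.
#' @return List: \code{oddsRatio}, \code{p}.
#' @export
fisherExact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  kk <- a + c         # column 1 margin
  if (m + n == 0 || kk == 0 || (b + d) == 0 || m == 0 || n == 0)
    stop("degenerate 2x2 table (zero margin)")
  enum <- fisherEnumeration(m, n, kk)
  list(oddsRatio = (a * d) / (b * c),
       p = enum$p[match(a, enum$a)])
}

#' Two-sided Fisher p for every table on fixed margins
#'
#' Enumerates the hypergeometric support for margins (row totals m, n;
#' first-column total k) and returns, for every realizable top-left count
#' a, the two-sided p-value: the sum of the probabilities of all support
#' points no more probable than a (relative tolerance 1e-7 on the
#' probability comparison).
#'
#' @param m,n Row margins.
#' @param k First-column margin.
#' @return data.frame with columns \code{a}, \code{prob}, \code{p}.
#' @export
fisherEnumeration <- function(m, n, k) {
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) -
    lchoose(m + n, k)
  prob <- exp(logp)
  p <- vapply(prob, function(pi) min(1, sum(prob[prob <= pi * (1 + 1e-7)])),
              numeric(1))
  data.frame(a = support, prob = prob, p = p)
}

#' Binomial rate comparison between two groups
#'
#' Exact binomial test of group a's event count against the rate observed
#' in group b (pinned null: H0 rate = events_b / n_b, n = n_a, two-sided).
#'
#' @param eventsA,nA Events and sites in group a.
#' @param eventsB,nB Events and sites in group b (defines the null rate).
#' @return List: \code{rateA}, \code{rateB}, \code{p}, \code{null}
#'   (description of the pinned H0 construction).
#' @export
rateComparison <- function(eventsA, nA, eventsB, nB) {
  stopifnot(eventsA >= 0, eventsB >= 0, nA > 0, nB > 0)
  p0 <- eventsB / nB
  p <- if (eventsA == 0 && eventsB == 0) 1
       else if (p0 <= 0) as.numeric(eventsA == 0)
       else if (p0 >= 1) as.numeric(eventsA == nA)
       else stats::binom.test(eventsA, nA, p = p0,
                              alternative = "two.sided")$p.value
  list(rateA = eventsA / nA, rateB = p0, p = p,
       null = sprintf("Binomial(n=%d, p=%.6g) from group b", nA, p0))
}

#' Project crosslink sites onto alignment columns
#'
#' Maps per-protein crosslink sites (ungapped positions) through the gaps
#' of a multiple sequence alignment and computes the per-column information
#' content IC = log2(20) - Shannon entropy of the residue frequencies
#' (gaps excluded from the frequencies).
#'
#' @param alignment Named character vector of aligned sequences (equal
#'   lengths, gaps as \code{-}), or a path to an aligned FASTA file.
#' @param sites data.frame with columns \code{protein} (alignment name),
#'   \code{position} (1-based ungapped) and \code{aa} (expected letter).
#' @return List with \code{profile} (per-column data.frame: \code{column},
#'   \code{ic}, \code{crosslinks}, \code{coverage}) and \code{mapped}
#'   (per-site column assignments).
#' @export
projectCrosslinks <- function(alignment, sites) {
  if (length(alignment) == 1 && file.exists(alignment)) {
    aln <- Biostrings::readAAStringSet(alignment)
    alignment <- stats::setNames(as.character(aln), names(aln))
  }
  lens <- unique(nchar(alignment))
  if (length(lens) != 1) stop("alignment sequences have unequal lengths")
  width <- lens
  chars <- lapply(alignment, function(s) strsplit(s, "")[[1]])

  ## per-column information content
  ic <- numeric(width)
  coverage <- integer(width)
  for (j in seq_len(width)) {
    col <- toupper(vapply(chars, `[`, "", j))
    col <- col[col %in% .AA_LETTERS]
    coverage[j] <- length(col)
    if (!length(col)) { ic[j] <- 0; next }
    f <- table(col) / length(col)
    ic[j] <- log2(20) + sum(f * log2(f))
  }

  crosslinks <- integer(width)
  mapped <- data.frame(protein = character(), position = integer(),
                       column = integer(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sites))) {
    nm <- sites$protein[i]
    if (!nm %in% names(alignment))
      stop("protein ", nm, " not in the alignment")
    sq <- chars[[nm]]
    ungapped <- cumsum(sq != "-")
    col <- match(sites$position[i], ifelse(sq != "-", ungapped, NA))
    if (is.na(col))
      stop("position ", sites$position[i], " beyond ungapped length of ",
           nm)
    if (toupper(sq[col]) != toupper(sites$aa[i]))
      stop("site letter mismatch for ", nm, " position ",
           sites$position[i], ": alignment has ", sq[col], ", site says ",
           sites$aa[i])
    crosslinks[col] <- crosslinks[col] + 1L
    mapped <- rbind(mapped, data.frame(protein = nm,
                                       position = sites$position[i],
                                       column = col,
                                       stringsAsFactors = FALSE))
  }
  list(profile = data.frame(column = seq_len(width), ic = ic,
                            crosslinks = crosslinks, coverage = coverage),
       mapped = mapped)
}
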