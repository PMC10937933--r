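## Synthetic minority oversampling (SMOTE).
##
## Implemented from the defining interpolation rule: each synthetic sample
## is x + u * (x' - x) with u ~ Uniform(0, 1) and x' a uniformly chosen
## member of x's k nearest minority neighbors (Euclidean distance).

#' @keywords internal
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' SMOTE oversampling of a minority class
#'
#' Generates \code{n} synthetic minority rows by linear interpolation
#' between each seed row and one of its k nearest minority neighbors.
#' Every synthetic row lies on a segment between two minority rows, hence
#' inside the minority convex hull.
#'
#' @param x Numeric matrix of minority rows (>= 2 rows).
#' @param n Number of synthetic rows to generate.
#' @param k Number of nearest neighbors (default 5); reduced with a warning
#'   when fewer minority rows are available.
#' @param seed Optional RNG seed.
#' @return Numeric matrix of \code{n} synthetic rows.
#' @export
smoteOversample <- function(x, n, k = 5, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2)
    stop("SMOTE needs at least 2 minority rows to interpolate")
  if (k >= nrow(x)) {
    k <- nrow(x) - 1
    warning("k reduced to ", k, " (minority count ", nrow(x), ")")
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- matrix(0L, nrow(x), k)
  for (i in seq_len(nrow(x))) nn[i, ] <- order(d[i, ])[seq_len(k)]
  .withSeed(seed, {
    base <- sample.int(nrow(x), n, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, n, replace = TRUE))]
    u <- stats::runif(n)
    x[base, , drop = FALSE] +
      u * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])
  })
}

#' Balance a labeled dataset with SMOTE
#'
#' Oversamples the minority class to the target minority:majority ratio
#' (default 1:1) and returns the augmented feature matrix and labels.
#'
#' @param x Feature matrix.
#' @param y Binary labels (0/1).
#' @param ratio Target minority/majority ratio after oversampling
#'   (default 1).
#' @param k Neighbors for \code{\link{smoteOversample}}.
#' @param seed Optional RNG seed.
#' @return List with \code{x}, \code{y} (augmented) and
#'   \code{nSynthetic}.
#' @export
smoteBalance <- function(x, y, ratio = 1, k = 5, seed = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0, 1)))
  minority <- if (tab["1"] <= tab["0"]) 1L else 0L
  nMin <- sum(y == minority)
  nMaj <- length(y) - nMin
  need <- max(0, round(ratio * nMaj) - nMin)
  if (need == 0 || nMin < 2)
    return(list(x = x, y = y, nSynthetic = 0L))
  syn <- smoteOversample(x[y == minority, , drop = FALSE], need, k = k,
                         seed = seed)
  list(x = rbind(x, syn), y = c(y, rep(minority, need)),
       nSynthetic = as.integer(need))
}
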