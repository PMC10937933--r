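## Independent oracles used across the suite. These deliberately avoid the
## package's internal code paths.

## four-point dihedral via explicit normal-vector construction
oracleDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  m1 <- pracma::cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

## pseudorotation phase from five ring atom positions: dihedrals first,
## then the closed-form phase relation, evaluated step by step
oraclePhase <- function(xyz) {
  tor <- function(a, b, c, d)
    oracleDihedral(xyz[a, ], xyz[b, ], xyz[c, ], xyz[d, ])
  nu0 <- tor("C4'", "O4'", "C1'", "C2'")
  nu1 <- tor("O4'", "C1'", "C2'", "C3'")
  nu2 <- tor("C1'", "C2'", "C3'", "C4'")
  nu3 <- tor("C2'", "C3'", "C4'", "O4'")
  nu4 <- tor("C3'", "C4'", "O4'", "C1'")
  num <- (nu4 + nu1) - (nu3 + nu0)
  den <- 2 * nu2 * (sin(36 * pi / 180) + sin(72 * pi / 180))
  P <- atan(num / den) * 180 / pi
  if (nu2 < 0) P <- P + 180
  P %% 360
}

## smallest-principal-axis plane normal by eigen-decomposition of the
## coordinate covariance
oraclePlaneNormal <- function(xyz) {
  centered <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(centered), symmetric = TRUE)
  n <- ev$vectors[, 3]
  if (abs(n[3]) > 1e-9) { if (n[3] < 0) n <- -n }
  else if (abs(n[1]) > 1e-9) { if (n[1] < 0) n <- -n }
  else if (n[2] < 0) n <- -n
  n
}

## brute-force all-pairs residue contact table
oracleContacts <- function(structure, cutoff = 4.5) {
  at <- atoms(structure, heavyOnly = TRUE)
  cls <- chainClasses(structure)
  at$key <- paste(at$chain, at$resno,
                  ifelse(at$insert == "", ".", at$insert), sep = ":")
  rna <- at[cls[at$chain] == "RNA" & at$kind == "ribonucleotide", ]
  prot <- at[cls[at$chain] == "protein" & at$kind == "amino-acid", ]
  out <- list()
  for (nk in unique(rna$key)) for (ak in unique(prot$key)) {
    a <- as.matrix(rna[rna$key == nk, c("x", "y", "z")])
    b <- as.matrix(prot[prot$key == ak, c("x", "y", "z")])
    dmin <- Inf
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      dmin <- min(dmin, sqrt(sum((a[i, ] - b[j, ])^2)))
    if (dmin <= cutoff + 1e-9)
      out[[length(out) + 1]] <- data.frame(nt = nk, aa = ak,
                                           minDistance = dmin)
  }
  if (!length(out)) return(data.frame(nt = character(), aa = character(),
                                      minDistance = numeric()))
  o <- do.call(rbind, out)
  o[order(o$nt, o$aa), ]
}

## Needleman-Wunsch global alignment DP (match +1 / mismatch -1 / gap -2)
## returning, for a 1-based position in seq a, the aligned position in b
oracleAlignMap <- function(a, b, pos) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -2 * (0:n); S[1, ] <- -2 * (0:m)
  for (i in 1:n) for (j in 1:m)
    S[i + 1, j + 1] <- max(S[i, j] + ifelse(A[i] == B[j], 1, -1),
                           S[i, j + 1] - 2, S[i + 1, j] - 2)
  ## traceback
  i <- n; j <- m; map <- rep(NA_integer_, n)
  while (i > 0 && j > 0) {
    if (S[i + 1, j + 1] == S[i, j] + ifelse(A[i] == B[j], 1, -1)) {
      map[i] <- j; i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1] - 2) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  map[pos]
}

## 2-D point-in-convex-hull test by winding over the hull polygon
oracleInHull <- function(points, query, tol = 1e-9) {
  hull <- points[grDevices::chull(points), , drop = FALSE]
  n <- nrow(hull)
  apply(query, 1, function(q) {
    signs <- vapply(seq_len(n), function(i) {
      a <- hull[i, ]; b <- hull[(i %% n) + 1, ]
      (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
    }, numeric(1))
    all(signs >= -tol) || all(signs <= tol)
  })
}

## rigid-body transform of a ComplexStructure
rigidTransform <- function(structure, axis = c(1, 2, 3), angle = 37,
                           shift = c(5, -3, 11)) {
  at <- atoms(structure)
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  newComplexStructure(at[, c("chain", "resno", "insert", "resid", "elety",
                             "elesy", "x", "y", "z", "o", "alt")],
                      accession = structure@accession)
}
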