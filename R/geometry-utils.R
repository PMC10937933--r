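## Low-level vector geometry shared by the interface annotators.

#' @keywords internal
.vnorm <- function(v) sqrt(sum(v * v))

#' @keywords internal
.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

#' Dihedral angle of four points, in degrees in (-180, 180]
#' @keywords internal
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2u <- .unit(b2)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / .vnorm(b2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Least-squares plane through a set of points
#'
#' Fits the total-least-squares plane through \code{>= 3} points by singular
#' value decomposition of the centered coordinates. The returned unit normal
#' follows a pinned sign convention (positive z component; if the z component
#' is ~0, positive x; then positive y) so plane orientation is deterministic.
#'
#' @param xyz Numeric matrix with one row per atom and columns x, y, z
#'   (coordinates in Angstrom); at least 3 non-collinear rows.
#' @return A list with \code{centroid} (length-3), \code{normal} (unit
#'   length-3) and \code{rmsd} (root-mean-square out-of-plane deviation, in
#'   Angstrom).
#' @examples
#' hexagon <- cbind(cos(seq(0, 300, 60) * pi / 180),
#'                  sin(seq(0, 300, 60) * pi / 180), 1)
#' fitPlane(hexagon)$normal
#' @export
fitPlane <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) stop("fitPlane needs at least 3 atoms")
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  sv <- svd(centered)
  ## collinear input: the two largest singular values do not span a plane
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("degenerate plane: input atoms are collinear")
  normal <- sv$v[, 3]
  if (abs(normal[3]) > 1e-9) {
    if (normal[3] < 0) normal <- -normal
  } else if (abs(normal[1]) > 1e-9) {
    if (normal[1] < 0) normal <- -normal
  } else if (normal[2] < 0) {
    normal <- -normal
  }
  rmsd <- sqrt(mean((centered %*% normal)^2))
  list(centroid = centroid, normal = as.numeric(normal), rmsd = rmsd)
}

#' Acute angle between two plane normals, degrees in [0, 90]
#' @keywords internal
.interplaneAngle <- function(n1, n2) {
  ct <- abs(sum(.unit(n1) * .unit(n2)))
  acos(min(1, ct)) * 180 / pi
}

#' Rotation matrix about a unit axis by angle (degrees)
#' @keywords internal
.rotationMatrix <- function(axis, angle) {
  u <- .unit(axis)
  th <- angle * pi / 180
  c <- cos(th); s <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c + ux^2 * (1 - c),       ux * uy * (1 - c) - uz * s, ux * uz * (1 - c) + uy * s,
    uy * ux * (1 - c) + uz * s, c + uy^2 * (1 - c),       uy * uz * (1 - c) - ux * s,
    uz * ux * (1 - c) - uy * s, uz * uy * (1 - c) + ux * s, c + uz^2 * (1 - c)
  ), nrow = 3, byrow = TRUE)
}
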