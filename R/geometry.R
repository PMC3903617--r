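# 3D geometry primitives: internal-coordinate atom placement (NeRF),
# dihedral measurement, and the idealized C-beta construction.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Measure a proper dihedral angle
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (angstrom).
#' @return Signed dihedral in degrees, in (-180, 180].
#' @keywords internal
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(p1, p2, p3) {
  u <- unit(p1 - p2)
  v <- unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Place an atom from internal coordinates (natural extension reference frame)
#'
#' Position X such that |X - C| = bond, angle(B, C, X) = angle and
#' dihedral(A, B, C, X) = torsion.
#'
#' @param A,B,C numeric 3-vectors of the three reference atoms.
#' @param bond bond length C-X, angstrom.
#' @param angle bond angle B-C-X, degrees.
#' @param torsion dihedral A-B-C-X, degrees.
#' @keywords internal
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(C - B)
  ab <- B - A
  n <- unit(vcross(ab, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Idealized C-beta from backbone N, CA, C (standard tetrahedral
# reconstruction; constants give L-amino-acid chirality).
ideal_cb <- function(N, CA, C) {
  b <- CA - N
  c <- C - CA
  a <- vcross(b, c)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * c + CA
}

# Rigid-body helpers (used by invariance tests and generators)
rotation_matrix <- function(axis, theta_deg) {
  u <- unit(axis)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

#' Apply a rigid-body transformation to a complex structure
#'
#' @param structure a `cstruct` object.
#' @param rot 3x3 rotation matrix (default identity).
#' @param shift numeric 3-vector translation (default zero).
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rot = diag(3), shift = c(0, 0, 0)) {
  stopifnot(inherits(structure, "cstruct"))
  structure$xyz <- structure$xyz %*% t(rot) +
    matrix(shift, nrow(structure$xyz), 3, byrow = TRUE)
  structure
}
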