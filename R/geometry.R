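# Low-level 3D geometry: internal-coordinate atom placement, dihedral
# measurement and Kabsch superposition. Coordinates are in Angstrom
# throughout; angles and torsions in degrees.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Place an atom from internal coordinates
#'
#' NeRF-style placement: the new atom `X` is bonded to `C` at distance
#' `bond`, with bond angle `X-C-B` equal to `angle` and torsion
#' `X-C-B-A` equal to `torsion`, so that
#' `measure_dihedral(A, B, C, X) == torsion`.
#'
#' @param A,B,C numeric length-3 reference coordinates (Angstrom).
#' @param bond bond length C-X in Angstrom.
#' @param angle bond angle B-C-X in degrees.
#' @param torsion dihedral A-B-C-X in degrees.
#' @return numeric length-3 coordinates of the new atom.
#' @keywords internal
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  C + (-bond * cos(ang)) * bc +
    (bond * sin(ang) * cos(tor)) * m +
    (bond * sin(ang) * sin(tor)) * n
}

#' Measure a dihedral angle
#'
#' Signed torsion angle of the four points `p1-p2-p3-p4`, in degrees in
#' `(-180, 180]`, using the IUPAC sign convention.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return angle in degrees.
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  c1 <- cross3(b1, b2)
  c2 <- cross3(b2, b3)
  y <- sum(cross3(c1, c2) * b2 / sqrt(sum(b2^2)))
  a <- atan2(y, sum(c1 * c2)) * 180 / pi
  if (a <= -180) a + 360 else a   # fold the -180 round-off onto +180
}

# Kabsch RMSD between two n x 3 coordinate matrices after optimal
# rigid-body superposition (rotation + translation, no reflection).
kabsch_rmsd <- function(X, Y) {
  kabsch_core(center_coords(X), center_coords(Y))
}

# centered copy with the squared norm cached (hot path of clustering)
center_coords <- function(X) {
  Xc <- X - rep(colMeans(X), each = nrow(X))
  attr(Xc, "ssq") <- sum(Xc^2)
  Xc
}

kabsch_core <- function(Xc, Yc) {
  s <- svd(crossprod(Xc, Yc))
  e <- s$d
  e[3L] <- e[3L] * sign(det(s$v %*% t(s$u)))  # forbid reflections
  msd <- (attr(Xc, "ssq") + attr(Yc, "ssq") - 2 * sum(e)) / nrow(Xc)
  sqrt(max(msd, 0))
}
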