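# Small 3D geometry toolkit: vector helpers, bond/dihedral angles and the
# internal-coordinate (NeRF) atom placement used by the fixture builders.

#' @keywords internal
vnorm <- function(v) sqrt(sum(v * v))

#' @keywords internal
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Angle between three points
#'
#' @param a,b,c coordinate triples; the angle is at `b`.
#' @return angle in degrees, in \[0, 180\].
#' @export
angle3 <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 coordinate triples.
#' @return signed torsion in degrees, in (-180, 180\].
#' @export
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# cross product (kept local; avoids pulling a dependency for one primitive)
#' @keywords internal
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Returns the position `X` such that `|X - c3| = bond`,
#' `angle(X, c3, c2) = angle` and `dihedral(c1, c2, c3, X) = torsion`.
#'
#' @param c1,c2,c3 reference coordinates (c3 is the bonded parent).
#' @param bond bond length (Angstrom).
#' @param angle bond angle at `c3` (degrees).
#' @param torsion dihedral (degrees).
#' @return coordinate triple.
#' @export
place_atom <- function(c1, c2, c3, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  bc <- unit(c3 - c2)
  n <- unit(pracma_cross(c2 - c1, bc))
  m <- cbind(bc, pracma_cross(n, bc), n)
  as.numeric(c3 + m %*% d)
}
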