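## 3D geometry primitives: internal-coordinate atom placement (NeRF)
## and dihedral/angle measurement.  Coordinates are in Angstrom,
## angles in degrees.

DEG <- pi / 180

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame (NeRF) construction: given three
#' previously placed atoms `a`, `b`, `c`, returns the position `d` with
#' bond length `|cd| = bond`, angle b-c-d = `angle` and dihedral
#' a-b-c-d = `dihedral`.
#'
#' @param a,b,c numeric 3-vectors (Angstrom).
#' @param bond bond length c-d, Angstrom.
#' @param angle bond angle b-c-d, degrees.
#' @param dihedral dihedral a-b-c-d, degrees.
#' @return numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * DEG
  dih <- dihedral * DEG
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), -sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Measure a dihedral angle
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return dihedral p1-p2-p3-p4 in degrees, in (-180, 180].
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Measure a bond angle
#'
#' @param p1,p2,p3 numeric 3-vectors; the angle is at `p2`.
#' @return angle in degrees.
#' @export
measure_angle <- function(p1, p2, p3) {
  v1 <- unit(p1 - p2)
  v2 <- unit(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2)))) / DEG
}

#' Wrap angles into (-180, 180]
#' @param x numeric vector of angles, degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x <= -180] <- x[x <= -180] + 360
  x
}
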