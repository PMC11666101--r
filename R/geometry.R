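# Small 3D geometry kit: internal-coordinate atom placement (NeRF),
# rigid-body superposition on three points, torsion measurement.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate (zero-length) vector")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Places atom D given three reference atoms so that `|C-D| = bond`,
#' the angle B-C-D equals `angle` and the dihedral A-B-C-D equals `torsion`.
#'
#' @param a,b,c Numeric xyz of the three reference atoms (A most distal).
#' @param bond Bond length (Angstrom).
#' @param angle Bond angle at C (degrees).
#' @param torsion Dihedral A-B-C-D (degrees).
#' @return Numeric xyz of the placed atom.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(
    -cos(ang),
    sin(ang) * cos(tor),
    sin(ang) * sin(tor)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Measure a dihedral angle
#'
#' @param a,b,c,d Numeric xyz of four atoms.
#' @return Dihedral A-B-C-D in degrees, in (-180, 180].
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Rigid transform (rotation + translation) mapping three source points onto
# three target points exactly (assumes congruent triangles; small template
# mismatch is absorbed by frame construction, not least squares).
frame_from_points <- function(p1, p2, p3) {
  e1 <- unit(p2 - p1)
  v <- p3 - p1
  e2 <- unit(v - sum(v * e1) * e1)
  e3 <- cross3(e1, e2)
  list(origin = p1, R = cbind(e1, e2, e3))
}

#' Transform coordinates between two 3-point frames
#' @keywords internal
transform_by_frames <- function(coords, src1, src2, src3, dst1, dst2, dst3) {
  fs <- frame_from_points(src1, src2, src3)
  fd <- frame_from_points(dst1, dst2, dst3)
  n <- nrow(coords)
  local <- (coords - matrix(fs$origin, n, 3, byrow = TRUE)) %*% fs$R
  local %*% t(fd$R) + matrix(fd$origin, n, 3, byrow = TRUE)
}

# Express coordinates in the local frame of three of their own points (the
# precomputable half of transform_by_frames).
to_local_frame <- function(coords, p1, p2, p3) {
  fs <- frame_from_points(p1, p2, p3)
  n <- nrow(coords)
  (coords - matrix(fs$origin, n, 3, byrow = TRUE)) %*% fs$R
}

# Place local-frame coordinates at a destination 3-point frame.
from_local_frame <- function(local, d1, d2, d3) {
  fd <- frame_from_points(d1, d2, d3)
  local %*% t(fd$R) + matrix(fd$origin, nrow(local), 3, byrow = TRUE)
}

# Rotation matrix about an arbitrary axis (unit vector), angle in degrees.
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  th <- angle * pi / 180
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}
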