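## Small vector helpers shared by the builders and the dipole model.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("geometry error: zero-length vector", call. = FALSE)
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed dihedral angle of four points
#'
#' Returns the torsion a-b-c-d in degrees using the IUPAC sign convention
#' (positive for a clockwise rotation of d relative to a when looking from
#' b towards c), in the interval (-180, 180].
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("geometry error: coincident atoms in dihedral", call. = FALSE)
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

## cross product (kept local; avoids importing pracma for one primitive)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Place an atom from internal coordinates
#'
#' Natural-extension-reference-frame placement: given three reference
#' positions `a`, `b`, `c`, returns the position `d` bonded to `c` at
#' distance `bond`, with angle b-c-d equal to `angle` and torsion a-b-c-d
#' equal to `torsion`.
#'
#' @param a,b,c numeric length-3 reference positions (Angstrom).
#' @param bond bond length c-d in Angstrom (> 0).
#' @param angle bond angle b-c-d in degrees, in (0, 180).
#' @param torsion dihedral a-b-c-d in degrees.
#' @return Length-3 numeric position of the new atom.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  stopifnot(bond > 0, angle > 0, angle < 180)
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  bc <- vunit(c - b)
  n <- vunit(pracma_cross(bc, b - a))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(th),
          -bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## In-plane trigonal placement: substituent on `center` opposite the
## bisector of the bonds towards n1 and n2, at distance `bond`.
place_trigonal <- function(center, n1, n2, bond) {
  dir <- -(vunit(n1 - center) + vunit(n2 - center))
  center + bond * vunit(dir)
}

#' Measure a dihedral between four atoms of a structure
#'
#' @param structure a `helix_structure`.
#' @param a,b,c,d atom selectors: either integer row indices or character
#'   `"resid:atom_name"` references such as `"2:CA"`.
#' @return Signed dihedral in degrees, in (-180, 180].
#' @export
measure_dihedral <- function(structure, a, b, c, d) {
  idx <- vapply(list(a, b, c, d), resolve_atom, numeric(1), structure = structure)
  if (anyDuplicated(idx)) stop("geometry error: atoms must be distinct", call. = FALSE)
  xyz <- structure$atoms
  dihedral_angle(atom_xyz(structure, idx[1]), atom_xyz(structure, idx[2]),
                 atom_xyz(structure, idx[3]), atom_xyz(structure, idx[4]))
}
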