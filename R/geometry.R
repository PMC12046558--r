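#' Unweighted centroid of a set of atoms
#'
#' Ring "centroids" throughout the package are plain arithmetic means of
#' heavy-atom coordinates, with no mass weighting.
#'
#' @param frame a `Frame`.
#' @param atom_ids integer vector of 1-based atom indices (>= 1 entry).
#' @return numeric length-3 vector (Angstrom).
#' @export
centroid <- function(frame, atom_ids) {
  atom_ids <- as.integer(atom_ids)
  if (length(atom_ids) < 1L) stop("empty atom index list", call. = FALSE)
  if (any(atom_ids < 1L | atom_ids > nrow(frame$xyz))) {
    stop("atom index out of range", call. = FALSE)
  }
  colMeans(frame$xyz[atom_ids, , drop = FALSE])
}

# torsion from four points, IUPAC sign convention (cis = 0, trans = 180,
# positive clockwise looking from j towards k); range (-180, 180]
.dihedral_xyz <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  c12 <- .cross3(b1, b2)
  c23 <- .cross3(b2, b3)
  if (.vnorm(c12) < 1e-8 || .vnorm(c23) < 1e-8) {
    stop("undefined torsion: three consecutive atoms are collinear",
         call. = FALSE)
  }
  x <- sum(c12 * c23)
  y <- sum(.cross3(c12, c23) * b2) / .vnorm(b2)
  ang <- atan2(y, x) * 180 / pi
  wrap_angle(ang)
}

#' Dihedral (torsion) angle between four atoms
#'
#' @param frame a `Frame`.
#' @param i,j,k,l distinct 1-based atom indices; the torsion is measured
#'   about the j-k bond.
#' @return angle in degrees in (-180, 180]. The value is invariant under
#'   full path reversal (`dihedral(l,k,j,i)` gives the same angle: the
#'   viewing direction and the endpoint roles both flip) and changes sign
#'   under mirror reflection of the coordinates.
#' @export
dihedral <- function(frame, i, j, k, l) {
  idx <- as.integer(c(i, j, k, l))
  if (anyDuplicated(idx)) stop("dihedral indices must be distinct", call. = FALSE)
  if (any(idx < 1L | idx > nrow(frame$xyz))) {
    stop("atom index out of range", call. = FALSE)
  }
  .dihedral_xyz(frame$xyz[idx[1L], ], frame$xyz[idx[2L], ],
                frame$xyz[idx[3L], ], frame$xyz[idx[4L], ])
}

# Orientation of the Re side of the trigonal carbene: the side from which
# the priority sequence Rh > ester C > aryl ipso C appears clockwise.
# For unit substituent directions u1, u2, u3 from the carbene carbon, the
# sum of pairwise cross products points to the side from which the sequence
# appears counterclockwise; Re is the opposite side.
.re_direction <- function(u1, u2, u3) {
  s <- .cross3(u1, u2) + .cross3(u2, u3) + .cross3(u3, u1)
  ns <- .vnorm(s)
  if (ns < 1e-8) {
    stop("degenerate carbene plane: substituent directions have no orientation",
         call. = FALSE)
  }
  -s / ns
}

#' Least-squares carbene plane with Re-oriented normal
#'
#' Fits a plane through the carbene carbon and its three substituent anchor
#' atoms (the carbene-bearing Rh, the ester carbonyl carbon and the ipso
#' carbon of the donor aryl ring, taken as the first entry of
#' `aryl_ring_idx`). A least-squares plane over the four atoms, rather than
#' an exact three-point plane, keeps the face split stable when snapshots
#' show slight pyramidalization at the carbene carbon. The unit normal is
#' oriented toward the Re side: the side from which the fixed priority
#' sequence Rh > ester carbon > aryl carbon appears clockwise.
#'
#' @param frame a `Frame`.
#' @param topo a `TopologyMap`.
#' @return list with `normal` (unit length-3 vector, pointing to the Re
#'   side) and `point` (a point on the plane).
#' @export
carbene_plane <- function(frame, topo) {
  xyz <- frame$xyz
  cc <- xyz[topo$carbene_c_idx, ]
  u1 <- .unit(xyz[topo$rh_carbene_idx, ] - cc, "carbene-Rh direction")
  u2 <- .unit(xyz[topo$ester_c_idx, ] - cc, "carbene-ester direction")
  u3 <- .unit(xyz[topo$aryl_ring_idx[1L], ] - cc, "carbene-aryl direction")
  n_re <- .re_direction(u1, u2, u3)
  pts <- xyz[c(topo$carbene_c_idx, topo$rh_carbene_idx, topo$ester_c_idx,
               topo$aryl_ring_idx[1L]), , drop = FALSE]
  m <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, m))
  normal <- sv$v[, 3L]
  if (sum(normal * n_re) < 0) normal <- -normal
  list(normal = normal, point = m)
}

#' Assign a point to the Re or Si face of the carbene
#'
#' The two prochiral faces of the trigonal carbene carbon are told apart by
#' the standard CIP construction: looking at the carbene plane from the Re
#' side, the substituent priority sequence Rh > ester carbonyl carbon >
#' aryl ipso carbon runs clockwise. Priorities are fixed for this chemotype
#' (Rh dominates by atomic number; the ester carbon outranks the aryl
#' carbon by its (O,O,O) > (C,C,C) duplicated-atom set), so no general CIP
#' engine is needed. Points closer to the plane than `ambiguity_band` are
#' labelled `"ambiguous"` and excluded from face-resolved statistics.
#'
#' @param frame a `Frame`.
#' @param topo a `TopologyMap`.
#' @param point numeric length-3 query point (Angstrom).
#' @param ambiguity_band half-width (Angstrom) of the near-plane dead zone;
#'   default 0.5.
#' @return an object of class `FaceAssignment`: list with `face` (`"Re"`,
#'   `"Si"` or `"ambiguous"`) and `signed_offset` (Angstrom, positive toward
#'   Re). Mirror-reflecting all coordinates swaps Re and Si.
#' @export
assign_face <- function(frame, topo, point, ambiguity_band = 0.5) {
  pl <- carbene_plane(frame, topo)
  off <- sum((point - pl$point) * pl$normal)
  face <- if (abs(off) < ambiguity_band) "ambiguous" else
    if (off > 0) "Re" else "Si"
  structure(list(face = face, signed_offset = off), class = "FaceAssignment")
}

#' @export
print.FaceAssignment <- function(x, ...) {
  cat(sprintf("<FaceAssignment: %s (offset %+.3f A)>\n", x$face, x$signed_offset))
  invisible(x)
}

#' Reflect a frame through a coordinate plane
#'
#' Diagnostic helper: mirror-reflection flips molecular chirality, so every
#' non-ambiguous Re assignment becomes Si and the d(Re)/d(Si) descriptors
#' swap exactly. Useful for antisymmetry checks of a face-resolved analysis.
#'
#' @param frame a `Frame`.
#' @param axis coordinate axis whose sign is flipped (reflection through the
#'   plane normal to it): `"x"`, `"y"` or `"z"`.
#' @return the reflected `Frame`.
#' @export
reflect_frame <- function(frame, axis = c("y", "x", "z")) {
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  frame$xyz[, k] <- -frame$xyz[, k]
  frame
}

#' Reflect every frame of a trajectory
#' @param traj a `Trajectory`.
#' @inheritParams reflect_frame
#' @return the reflected `Trajectory`.
#' @export
reflect_trajectory <- function(traj, axis = c("y", "x", "z")) {
  axis <- match.arg(axis)
  traj$frames <- lapply(traj$frames, reflect_frame, axis = axis)
  traj
}
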