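#' Ligand-carbene centroid distances split by prochiral face
#'
#' The steric metric at the heart of the facial-selectivity analysis: each
#' arm's blocking-ring centroid is assigned to the Re or Si face of the
#' carbene with [assign_face()], and d(face) is the minimum centroid-to-
#' centroid distance from the carbene donor benzene-ring centroid to the
#' blocking-ring centroids on that face. A face with no non-ambiguous arm
#' yields `NA` (reported, never imputed).
#'
#' @param frame a `Frame`.
#' @param topo a `TopologyMap`.
#' @param ambiguity_band near-plane dead zone passed to [assign_face()]
#'   (Angstrom).
#' @return list with `d_re`, `d_si` (Angstrom or `NA`), `closest_arm_re`,
#'   `closest_arm_si` (arm index or `NA`), `arm_face` (length-4 character),
#'   `arm_dist` (length-4, centroid distance to the donor-ring centroid) and
#'   `d_arm_to_carbene_c` (length-4, blocking-ring centroid to carbene
#'   carbon).
#' @export
ligand_carbene_distances <- function(frame, topo, ambiguity_band = 0.5) {
  pl <- carbene_plane(frame, topo)  # errors here mean a degenerate frame
  donor_cen <- centroid(frame, topo$aryl_ring_idx)
  cc <- frame$xyz[topo$carbene_c_idx, ]
  arm_face <- character(4L)
  arm_dist <- numeric(4L)
  d_cc <- numeric(4L)
  for (i in 1:4) {
    bc <- centroid(frame, topo$arms[[i]]$blocking_ring_idx)
    off <- sum((bc - pl$point) * pl$normal)
    arm_face[i] <- if (abs(off) < ambiguity_band) "ambiguous" else
      if (off > 0) "Re" else "Si"
    arm_dist[i] <- .vnorm(bc - donor_cen)
    d_cc[i] <- .vnorm(bc - cc)
  }
  pick <- function(face) {
    idx <- which(arm_face == face)
    if (length(idx) == 0L) return(list(d = NA_real_, arm = NA_integer_))
    j <- idx[which.min(arm_dist[idx])]
    list(d = arm_dist[j], arm = j)
  }
  re <- pick("Re")
  si <- pick("Si")
  list(d_re = re$d, d_si = si$d,
       closest_arm_re = re$arm, closest_arm_si = si$arm,
       arm_face = arm_face, arm_dist = arm_dist,
       d_arm_to_carbene_c = d_cc)
}

#' Per-frame steric descriptor series
#'
#' Runs the face-resolved distance metric, the four arm torsions and
#' (optionally) the percent buried volume over every frame of a trajectory.
#' Frames with degenerate geometry are kept in the table with `NA` values;
#' the skip reasons are attached as the `"skipped"` attribute.
#'
#' @param traj a `Trajectory`.
#' @param topo a `TopologyMap` (torsion references resolved from the first
#'   frame when absent).
#' @param ambiguity_band Angstrom; see [assign_face()].
#' @param vbur logical; also compute [buried_volume()] per frame (slower).
#' @param vbur_args list of extra arguments passed to [buried_volume()].
#' @return a data frame of class `DescriptorSeries` with one row per frame:
#'   `frame`, `d_re`, `d_si`, `closest_arm_re`, `closest_arm_si`,
#'   `theta_1`..`theta_4`, `d_cc_1`..`d_cc_4`, and `pct_vbur` when requested.
#' @export
descriptor_series <- function(traj, topo, ambiguity_band = 0.5, vbur = FALSE,
                              vbur_args = list()) {
  topo <- resolve_theta_ref(topo, traj)
  skipped <- character(0)
  rows <- vector("list", n_frames(traj))
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    row <- list(frame = fr$frame_index,
                d_re = NA_real_, d_si = NA_real_,
                closest_arm_re = NA_integer_, closest_arm_si = NA_integer_)
    lcd <- tryCatch(
      ligand_carbene_distances(fr, topo, ambiguity_band = ambiguity_band),
      error = function(e) conditionMessage(e)
    )
    if (is.character(lcd)) {
      skipped <- c(skipped, sprintf("frame %d: %s", fr$frame_index, lcd))
      th <- rep(NA_real_, 4L)
      d_cc <- rep(NA_real_, 4L)
    } else {
      row$d_re <- lcd$d_re
      row$d_si <- lcd$d_si
      row$closest_arm_re <- lcd$closest_arm_re
      row$closest_arm_si <- lcd$closest_arm_si
      d_cc <- lcd$d_arm_to_carbene_c
      th <- vapply(1:4, function(i) {
        q <- topo$arms[[i]]$dihedral_quad
        tryCatch(dihedral(fr, q[1L], q[2L], q[3L], q[4L]),
                 error = function(e) NA_real_)
      }, numeric(1))
    }
    names(th) <- paste0("theta_", 1:4)
    names(d_cc) <- paste0("d_cc_", 1:4)
    row <- c(row, as.list(th), as.list(d_cc))
    if (vbur) {
      row$pct_vbur <- tryCatch(
        do.call(buried_volume, c(list(frame = fr, topo = topo), vbur_args)),
        error = function(e) NA_real_
      )
    }
    rows[[k]] <- as.data.frame(row)
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  attr(out, "ambiguity_band") <- ambiguity_band
  class(out) <- c("DescriptorSeries", "data.frame")
  out
}

# Bondi van der Waals radii (Angstrom); elements missing from Bondi's set
# (notably transition metals) fall back to 2.0.
.BONDI <- c(H = 1.20, He = 1.40, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
            F = 1.47, Ne = 1.54, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
            Ar = 1.88, As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02,
            Te = 2.06, I = 1.98, Xe = 2.16)
.BONDI_DEFAULT <- 2.00

#' Percent buried volume around a sphere centre
#'
#' Standard grid-based percent buried volume: the fraction of uniform grid
#' points inside a probe sphere that fall within any non-excluded atom's
#' scaled Bondi van der Waals sphere, times 100. Defaults follow the
#' community-standard protocol: 3.5 Angstrom sphere, Bondi radii scaled by
#' 1.17, centred on the carbene-bearing Rh, with the two Rh atoms excluded.
#'
#' @param frame a `Frame`.
#' @param topo a `TopologyMap`, used for the centre and the Rh exclusion;
#'   may be `NULL` when `center_xyz` and `exclude_idx` are given explicitly.
#' @param sphere_radius probe sphere radius (Angstrom), > 0.
#' @param center `"carbene_rh"` (default) or `"carbene_c"`.
#' @param mesh grid spacing (Angstrom); must be <= `sphere_radius / 5`.
#' @param radii_scale scale factor applied to Bondi radii (default 1.17).
#' @param include_h logical; keep hydrogen atoms (default `TRUE`).
#' @param hemisphere_normal optional unit length-3 vector; when given, only
#'   grid points with a nonnegative projection on it are counted, i.e. the
#'   buried volume of that hemisphere. Pass the Re-oriented normal of
#'   [carbene_plane()] for a per-prochiral-face variant.
#' @param center_xyz explicit centre (length-3), overriding `center`.
#' @param exclude_idx explicit atom indices to exclude, overriding the Rh
#'   default.
#' @return percentage in \[0, 100\]; deterministic for a fixed mesh.
#' @export
buried_volume <- function(frame, topo = NULL, sphere_radius = 3.5,
                          center = c("carbene_rh", "carbene_c"), mesh = 0.1,
                          radii_scale = 1.17, include_h = TRUE,
                          hemisphere_normal = NULL,
                          center_xyz = NULL, exclude_idx = NULL) {
  center <- match.arg(center)
  if (!is.numeric(sphere_radius) || sphere_radius <= 0) {
    stop("sphere_radius must be > 0", call. = FALSE)
  }
  if (!is.numeric(mesh) || mesh <= 0 || mesh > sphere_radius / 5) {
    stop("mesh must be positive and at most sphere_radius / 5", call. = FALSE)
  }
  if (is.null(center_xyz)) {
    if (is.null(topo)) stop("either topo or center_xyz is required", call. = FALSE)
    center_xyz <- switch(center,
                         carbene_rh = frame$xyz[topo$rh_carbene_idx, ],
                         carbene_c = frame$xyz[topo$carbene_c_idx, ])
  }
  if (is.null(exclude_idx)) {
    exclude_idx <- if (!is.null(topo)) {
      c(topo$rh_carbene_idx, topo$rh_distal_idx)
    } else integer(0)
  }
  keep <- setdiff(seq_len(nrow(frame$xyz)), exclude_idx)
  if (!include_h) keep <- keep[toupper(frame$elements[keep]) != "H"]

  g <- seq(-sphere_radius, sphere_radius, by = mesh)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  r2 <- rowSums(pts * pts)
  pts <- pts[r2 <= sphere_radius^2, , drop = FALSE]
  if (!is.null(hemisphere_normal)) {
    hn <- .unit(hemisphere_normal, "hemisphere normal")
    pts <- pts[pts %*% hn >= 0, , drop = FALSE]
  }
  if (length(keep) == 0L) return(0)

  ele <- frame$elements[keep]
  key <- paste0(toupper(substr(ele, 1L, 1L)), tolower(substring(ele, 2L)))
  radii <- unname(.BONDI[key])
  unknown <- is.na(radii)
  if (any(unknown)) {
    warning("no Bondi radius for element(s) ",
            paste(unique(key[unknown]), collapse = ", "),
            "; using ", .BONDI_DEFAULT, " A", call. = FALSE)
    radii[unknown] <- .BONDI_DEFAULT
  }
  radii <- radii * radii_scale

  covered <- rep(FALSE, nrow(pts))
  xyz <- frame$xyz[keep, , drop = FALSE]
  for (j in seq_along(keep)) {
    if (all(covered)) break
    d <- sweep(pts, 2L, xyz[j, ] - center_xyz)
    covered <- covered | rowSums(d * d) <= radii[j]^2
  }
  100 * mean(covered)
}
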