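# Shared fixtures and independent oracles for the test suite.
# Everything here is built in code at test time; nothing is read from disk.

# Minimal carbene fragment: carbene carbon at `origin` with unit substituent
# directions u1 (Rh), u2 (ester C), u3 (aryl ipso C). Returns a Frame plus a
# topology stub carrying only the fields the face-assignment code reads
# (built directly, bypassing full-arm validation).
make_carbene_fragment <- function(u1, u2, u3, origin = c(0, 0, 0),
                                  bond = 1.5) {
  xyz <- rbind(origin,
               origin + bond * u1,
               origin + bond * u2,
               origin + bond * u3)
  fr <- new_frame(c("C", "Rh", "C", "C"), xyz)
  topo <- structure(list(
    rh_carbene_idx = 2L, rh_distal_idx = 2L, carbene_c_idx = 1L,
    ester_c_idx = 3L, aryl_ring_idx = 4L, arms = list()
  ), class = "TopologyMap")
  list(frame = fr, topo = topo)
}

# Independent Re/Si oracle: project the three substituent directions into
# the plane orthogonal to the query side `n` using an explicit right-handed
# screen basis and atan2 angles, and read off whether the priority sequence
# u1 -> u2 -> u3 wraps counterclockwise as seen from +n. Clockwise from the
# query side means the query side is Re. Shares no code with the
# cross-product-sum used by the implementation.
oracle_face <- function(u1, u2, u3, n) {
  n <- n / sqrt(sum(n^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  ang <- vapply(list(u1, u2, u3), function(u) {
    atan2(sum(u * e2), sum(u * e1))
  }, numeric(1))
  d12 <- (ang[2] - ang[1]) %% (2 * pi)
  d23 <- (ang[3] - ang[2]) %% (2 * pi)
  ccw_from_n <- (d12 + d23) < 2 * pi
  if (ccw_from_n) "Si" else "Re"
}

# uniform random unit vector
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# random rotation matrix via QR of a Gaussian matrix, det forced to +1
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rotation <- function(frame, R, shift = c(0, 0, 0)) {
  frame$xyz <- sweep(frame$xyz %*% t(R), 2L, -shift)
  frame
}

# all 16 pure two-sided arm-state specs plus 8 primed variants
all_state_specs <- function() {
  specs <- list()
  for (i in 0:15) {
    specs[[length(specs) + 1L]] <- c("a", "b")[1 + ((i %/% c(1L, 2L, 4L, 8L)) %% 2L)]
  }
  for (k in 1:4) {
    s <- rep("a", 4); s[seq_len(k)] <- "a'"
    specs[[length(specs) + 1L]] <- s
    s <- rep("b", 4); s[seq_len(k)] <- "b'"
    specs[[length(specs) + 1L]] <- s
  }
  specs
}

# Brute-force face-resolved distance oracle: re-derives the face split from
# scratch (exact three-point plane through Rh / ester C / ipso C, oriented
# with oracle_face) and scans arms x faces with a plain loop.
oracle_ligand_distances <- function(frame, topo, ambiguity_band = 0.5) {
  xyz <- frame$xyz
  cc <- xyz[topo$carbene_c_idx, ]
  u1 <- (xyz[topo$rh_carbene_idx, ] - cc)
  u2 <- (xyz[topo$ester_c_idx, ] - cc)
  u3 <- (xyz[topo$aryl_ring_idx[1], ] - cc)
  u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2)); u3 <- u3 / sqrt(sum(u3^2))
  # plane through the three substituent anchor tips (exact, not least squares)
  p1 <- cc + u1; p2 <- cc + u2; p3 <- cc + u3
  v1 <- p2 - p1; v2 <- p3 - p1
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  if (oracle_face(u1, u2, u3, nrm) != "Re") nrm <- -nrm
  donor <- colMeans(xyz[topo$aryl_ring_idx, , drop = FALSE])
  plane_pt <- (p1 + p2 + p3) / 3
  best <- list(Re = NA_real_, Si = NA_real_)
  for (i in 1:4) {
    bc <- colMeans(xyz[topo$arms[[i]]$blocking_ring_idx, , drop = FALSE])
    off <- sum((bc - plane_pt) * nrm)
    if (abs(off) < ambiguity_band) next
    face <- if (off > 0) "Re" else "Si"
    d <- sqrt(sum((bc - donor)^2))
    if (is.na(best[[face]]) || d < best[[face]]) best[[face]] <- d
  }
  best
}
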