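#' Specification for the synthetic paddlewheel-carbene generator
#'
#' Describes an idealized dirhodium tetracarboxylate-carbene ensemble with
#' planted ground truth: the rotational state of each of the four arms, the
#' blocking-ring centroid distances on the Re and Si faces, isotropic
#' Gaussian coordinate noise, and optionally a Markov chain switching
#' between whole-complex states. The internal core distances are idealized
#' defaults chosen for chemical plausibility and classification robustness,
#' not fits to any deposited structure; all are overridable.
#'
#' @param arm_states character vector of 4 tokens over `a`, `a'`, `b`, `b'`
#'   (alpha/beta side, prime = partial ~90 degree rotation).
#' @param d_block_re,d_block_si planted distance (Angstrom) from the carbene
#'   donor-ring centroid to the closest blocking-ring centroid on the Re and
#'   Si faces; must lie in (1.5, 7.5) so that it is realisable and remains
#'   the face minimum.
#' @param noise_sigma isotropic Gaussian noise, per atom per coordinate
#'   (Angstrom, >= 0).
#' @param n_frames number of frames to simulate.
#' @param markov optional list with `transition` (m x m row-stochastic
#'   matrix, m >= 2) and `states` (list of m lists, each optionally
#'   overriding `arm_states`, `d_block_re`, `d_block_si`).
#' @param seed integer RNG seed used by [simulate_trajectory()].
#' @param rh_rh_dist,rh_o_dist,rh_c_carbene_dist core distances (Angstrom).
#' @return an object of class `GeneratorSpec`.
#' @export
generator_spec <- function(arm_states = c("a", "a", "a", "a"),
                           d_block_re = 3.5, d_block_si = 6.0,
                           noise_sigma = 0.15, n_frames = 2000L,
                           markov = NULL, seed = 1L,
                           rh_rh_dist = 2.40, rh_o_dist = 2.04,
                           rh_c_carbene_dist = 2.00) {
  if (length(arm_states) != 4L) stop("arm_states must have 4 entries", call. = FALSE)
  .state_rank(arm_states)
  for (d in c(d_block_re, d_block_si)) {
    if (!is.finite(d) || d <= 1.5 || d >= 7.5) {
      stop("planted blocking distances must lie in (1.5, 7.5) Angstrom ",
           "(below that the ring would overlap the donor ring; above it the ",
           "away-face arms would become the face minimum)", call. = FALSE)
    }
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (any(c(rh_rh_dist, rh_o_dist, rh_c_carbene_dist) <= 0)) {
    stop("core distances must be positive", call. = FALSE)
  }
  if (!is.null(markov)) {
    P <- as.matrix(markov$transition)
    m <- nrow(P)
    if (m < 2L || ncol(P) != m) {
      stop("markov$transition must be a square matrix with >= 2 states",
           call. = FALSE)
    }
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
      stop("markov$transition rows must be nonnegative and sum to 1",
           call. = FALSE)
    }
    if (length(markov$states) != m) {
      stop("markov$states must have one entry per transition-matrix row",
           call. = FALSE)
    }
    markov$transition <- P
  }
  structure(
    list(arm_states = arm_states, d_block_re = d_block_re,
         d_block_si = d_block_si, noise_sigma = noise_sigma,
         n_frames = as.integer(n_frames), markov = markov,
         seed = as.integer(seed), rh_rh_dist = rh_rh_dist,
         rh_o_dist = rh_o_dist, rh_c_carbene_dist = rh_c_carbene_dist),
    class = "GeneratorSpec"
  )
}

# fixed internal idealized geometry of the generator (Angstrom / degrees);
# long lever arms on the torsion probe keep the angle jitter small at the
# generator's default coordinate noise
.GEN <- list(
  z_o = 2.0,         # axial offset of the coordinating carboxylate oxygens
  co_bond = 0.77,    # radial O-midpoint to carboxylate-C offset
  ca_bond = 2.6,     # carboxylate-C to alpha-C spacer
  stem_len = 4.0,    # alpha-C to imide-anchor (torsion probe) distance
  ring_r = 1.39,     # aromatic ring radius
  ester_bond = 1.48, # carbene-C to ester carbonyl C
  ipso_bond = 1.47,  # carbene-C to aryl ipso C
  alt_extra = 3.0,   # extra distance for the second same-face alpha arm
  beta_radial = 1.2, # radial offset of away-face (beta) blocking rings
  beta_drop = 2.6    # how far below the midplane beta rings sit
)

.state_psi <- function(token) {
  switch(token, "a" = 0, "a'" = 90, "b" = 180, "b'" = 270,
         stop("invalid arm state token: ", token, call. = FALSE))
}

#' Build the noise-free idealized template for a generator state
#'
#' Constructs one frame of an idealized paddlewheel-carbene complex — two
#' Rh on the z axis, four bridging carboxylate arms at 90 degree spacing
#' each carrying a six-membered blocking ring placed according to its
#' planted state, and an apical carbene carbon with a three-atom ester
#' proxy and a benzene donor ring — together with the matching topology
#' map. On the template, the conformer classifier recovers the planted
#' arm states exactly and the face-resolved distances equal the planted
#' blocking distances.
#'
#' @param spec a [generator_spec()].
#' @param state optional list overriding `arm_states`, `d_block_re`,
#'   `d_block_si` (used for Markov states).
#' @return list with `frame` (a `Frame`) and `topology` (a `TopologyMap`).
#' @export
build_template <- function(spec, state = NULL) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  arm_states <- state$arm_states %||% spec$arm_states
  d_re <- state$d_block_re %||% spec$d_block_re
  d_si <- state$d_block_si %||% spec$d_block_si
  .state_rank(arm_states)
  g <- .GEN
  zc <- spec$rh_rh_dist / 2
  if (spec$rh_o_dist^2 <= (zc - g$z_o)^2) {
    stop("infeasible spec: rh_o_dist too short for the paddlewheel core",
         call. = FALSE)
  }
  for (d in c(d_re, d_si)) {
    if (d <= g$ring_r) {
      stop("infeasible spec: blocking distance smaller than ring radius",
           call. = FALSE)
    }
  }

  ele <- character(0)
  xyz <- matrix(numeric(0), ncol = 3L)
  add <- function(e, p) {
    ele[length(ele) + 1L] <<- e
    xyz <<- rbind(xyz, p)
    length(ele)
  }
  dir_in_xz <- function(gamma_deg) {
    gam <- gamma_deg * pi / 180
    c(sin(gam), 0, -cos(gam))
  }
  hexagon <- function(center, w) {
    ref <- if (abs(w[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- .unit(.cross3(w, ref))
    e2 <- .cross3(w, e1)
    ang <- (0:5) * pi / 3
    t(vapply(ang, function(a) {
      center + g$ring_r * (cos(a) * e1 + sin(a) * e2)
    }, numeric(3)))
  }

  rh_c <- add("Rh", c(0, 0, zc))
  rh_d <- add("Rh", c(0, 0, -zc))
  cc_pos <- c(0, 0, zc + spec$rh_c_carbene_dist)
  cc <- add("C", cc_pos)
  # ester proxy: carbonyl carbon plus two oxygens, symmetric about y = 0
  est_pos <- cc_pos + g$ester_bond * dir_in_xz(120)
  est <- add("C", est_pos)
  add("O", est_pos + c(0.35, 1.0, 0.55))
  add("O", est_pos + c(0.35, -1.0, 0.55))
  # donor benzene ring, ipso first; ring plane spans the C-ipso direction
  # and the y axis, so its centroid lies exactly in the carbene plane
  d_aryl <- dir_in_xz(240)
  ring_cen <- cc_pos + (g$ipso_bond + g$ring_r) * d_aryl
  aryl_idx <- integer(6L)
  for (j in 0:5) {
    a <- pi + j * pi / 3
    p <- ring_cen + g$ring_r * (cos(a) * d_aryl + sin(a) * c(0, 1, 0))
    aryl_idx[j + 1L] <- add("C", p)
  }
  donor_cen <- ring_cen

  # which planted distance each arm carries: arms 1-2 sit on the y > 0 (Re)
  # side, arms 3-4 on the y < 0 (Si) side; within a face the first
  # alpha-family arm carries the planted face distance, a second one sits
  # farther out, and beta arms take fixed away-face positions
  R_o <- sqrt(spec$rh_o_dist^2 - (zc - g$z_o)^2)
  R_cc <- R_o + g$co_bond
  face_d <- c(d_re, d_re, d_si, d_si)
  is_alpha <- arm_states %in% c("a", "a'")
  arm_d <- numeric(4L)
  for (face_arms in list(1:2, 3:4)) {
    first <- TRUE
    for (k in face_arms) {
      if (is_alpha[k]) {
        arm_d[k] <- if (first) face_d[k] else face_d[k] + g$alt_extra
        first <- FALSE
      }
    }
  }

  arms <- vector("list", 4L)
  for (k in 1:4) {
    phi <- (45 + 90 * (k - 1)) * pi / 180
    r_hat <- c(cos(phi), sin(phi), 0)
    t_hat <- c(-sin(phi), cos(phi), 0)
    o1 <- add("O", R_o * r_hat + c(0, 0, g$z_o))
    o2 <- add("O", R_o * r_hat - c(0, 0, g$z_o))
    ccarb_pos <- R_cc * r_hat
    ccarb <- add("C", ccarb_pos)
    calpha_pos <- (R_cc + g$ca_bond) * r_hat
    calpha <- add("C", calpha_pos)
    psi <- .state_psi(arm_states[k]) * pi / 180
    stem_pos <- calpha_pos + g$stem_len * (cos(psi) * c(0, 0, 1) + sin(psi) * t_hat)
    nst <- add("N", stem_pos)
    if (is_alpha[k]) {
      u <- .unit(c(cos(phi), sin(phi), -0.2))
      ring_c <- donor_cen + arm_d[k] * u
    } else {
      ring_c <- (R_cc + g$ca_bond + g$beta_radial) * r_hat - c(0, 0, g$beta_drop)
    }
    hx <- hexagon(ring_c, .unit(ring_c - donor_cen))
    ring_idx <- integer(6L)
    for (j in 1:6) ring_idx[j] <- add("C", hx[j, ])
    arms[[k]] <- list(
      carboxylate_c_idx = ccarb, alpha_c_idx = calpha,
      dihedral_quad = c(o1, ccarb, calpha, nst),
      blocking_ring_idx = ring_idx,
      imide_group_idx = c(nst, ring_idx),
      theta_ref_deg = 0
    )
  }

  topo <- as_topology_map(list(
    rh_carbene_idx = rh_c, rh_distal_idx = rh_d, carbene_c_idx = cc,
    ester_c_idx = est, aryl_ring_idx = aryl_idx, arms = arms
  ))
  frame <- new_frame(ele, xyz, frame_index = 0L,
                     comment = paste0("idealized paddlewheel-carbene template ",
                                      paste(arm_states, collapse = ",")))
  validate_topology(topo, frame)
  list(frame = frame, topology = topo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a synthetic trajectory with planted ground truth
#'
#' Builds the idealized template(s) for the spec, samples a per-frame
#' Markov state sequence when a chain is given (initial state drawn from
#' the stationary distribution), and adds isotropic Gaussian coordinate
#' noise. Fully reproducible for a fixed `spec$seed`.
#'
#' @param spec a [generator_spec()].
#' @return list with `trajectory` (a `Trajectory`), `topology` (a
#'   `TopologyMap`) and `states` (integer planted state index per frame;
#'   all 1 without a Markov chain).
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  set.seed(spec$seed)
  if (is.null(spec$markov)) {
    templates <- list(build_template(spec))
    states <- rep(1L, spec$n_frames)
  } else {
    P <- spec$markov$transition
    m <- nrow(P)
    templates <- lapply(spec$markov$states, function(s) build_template(spec, s))
    pi0 <- stationary_distribution(P)
    states <- integer(spec$n_frames)
    states[1L] <- sample.int(m, 1L, prob = pi0)
    if (spec$n_frames > 1L) {
      for (t in 2:spec$n_frames) {
        states[t] <- sample.int(m, 1L, prob = P[states[t - 1L], ])
      }
    }
  }
  nat <- length(templates[[1L]]$frame$elements)
  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    tmpl <- templates[[states[t]]]$frame
    pos <- tmpl$xyz
    if (spec$noise_sigma > 0) {
      pos <- pos + matrix(stats::rnorm(nat * 3L, 0, spec$noise_sigma),
                          ncol = 3L)
    }
    frames[[t]] <- new_frame(tmpl$elements, pos, frame_index = t - 1L,
                             comment = sprintf("state %d", states[t]))
  }
  list(
    trajectory = trajectory(frames,
                            source = sprintf("rhface synthetic generator (seed %d)",
                                             spec$seed)),
    topology = templates[[1L]]$topology,
    states = states
  )
}

#' Stationary distribution of a row-stochastic transition matrix
#'
#' The left eigenvector of the transition matrix for eigenvalue 1,
#' normalised to sum to 1.
#'
#' @param P square row-stochastic matrix.
#' @return numeric stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  P <- as.matrix(P)
  ev <- eigen(t(P))
  k <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, k])
  v <- abs(v)
  v / sum(v)
}
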