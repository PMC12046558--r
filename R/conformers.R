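#' Resolve per-arm torsion references from a first frame
#'
#' Arms whose `theta_ref_deg` is `NA` (the topology file omitted it) get the
#' torsion measured on the supplied reference frame — by convention the
#' first frame of the trajectory, so that replicas analysed against the same
#' topology map share one reference.
#'
#' @param topo a `TopologyMap`.
#' @param x a `Frame` or `Trajectory` (first frame used).
#' @return the `TopologyMap` with all `theta_ref_deg` filled in.
#' @export
resolve_theta_ref <- function(topo, x) {
  if (inherits(x, "Trajectory")) x <- x$frames[[1L]]
  for (i in seq_along(topo$arms)) {
    if (is.na(topo$arms[[i]]$theta_ref_deg)) {
      q <- topo$arms[[i]]$dihedral_quad
      topo$arms[[i]]$theta_ref_deg <- dihedral(x, q[1L], q[2L], q[3L], q[4L])
    }
  }
  topo
}

#' Classify the rotational state of one carboxylate arm
#'
#' Two independent coordinates define the state. The side: an arm is `a`
#' (alpha) when the centroid of its imide blocking group lies on the carbene
#' side of the paddlewheel midplane — the plane through the Rh-Rh midpoint
#' with the Rh-Rh axis as normal, oriented toward the carbene-bearing Rh —
#' and `b` (beta) when it lies on the far side. The prime: the torsion
#' theta about the carboxylate-C to alpha-C bond is compared with the arm's
#' reference value, and a wrapped deviation inside `primed_window`
#' (default 60-120 degrees, capturing a partial ~90-degree ligand rotation)
#' marks the arm as primed. Full 180-degree rotations show up as a side
#' flip, not as a primed state.
#'
#' @param frame a `Frame`.
#' @param topo a `TopologyMap` with resolved `theta_ref_deg` (see
#'   [resolve_theta_ref()]).
#' @param arm_index arm number, 1 to 4.
#' @param primed_window numeric length-2: inclusive window (degrees) of
#'   absolute theta deviation classified as primed.
#' @param side_tol minimum projection (Angstrom) onto the Rh-Rh axis for an
#'   unambiguous side call.
#' @return an object of class `ArmState`: list with `side` (`"a"`/`"b"`),
#'   `primed` (logical), `token`, `theta_deg`, `delta_theta_deg`.
#' @export
arm_state <- function(frame, topo, arm_index, primed_window = c(60, 120),
                      side_tol = 1e-6) {
  stopifnot(arm_index %in% 1:4)
  arm <- topo$arms[[arm_index]]
  if (is.na(arm$theta_ref_deg)) {
    stop("theta_ref_deg unresolved; call resolve_theta_ref() first",
         call. = FALSE)
  }
  axis_vec <- frame$xyz[topo$rh_carbene_idx, ] - frame$xyz[topo$rh_distal_idx, ]
  a_hat <- .unit(axis_vec, "Rh-Rh axis")
  mid <- (frame$xyz[topo$rh_carbene_idx, ] + frame$xyz[topo$rh_distal_idx, ]) / 2
  cen <- centroid(frame, arm$imide_group_idx)
  proj <- sum((cen - mid) * a_hat)
  if (abs(proj) < side_tol) {
    stop(sprintf("arm %d imide centroid lies on the paddlewheel midplane",
                 arm_index), call. = FALSE)
  }
  side <- if (proj > 0) "a" else "b"
  q <- arm$dihedral_quad
  th <- dihedral(frame, q[1L], q[2L], q[3L], q[4L])
  dth <- abs(wrap_angle(th - arm$theta_ref_deg))
  primed <- dth >= primed_window[1L] && dth <= primed_window[2L]
  structure(
    list(side = side, primed = primed,
         token = paste0(side, if (primed) "'" else ""),
         theta_deg = th, delta_theta_deg = dth),
    class = "ArmState"
  )
}

#' Canonicalize a 4-arm state sequence
#'
#' The four arms of a paddlewheel are equivalent under cyclic rotation of
#' the arm order (but not reversal — the complex is chiral), so the
#' canonical label is the lexicographically smallest of the four cyclic
#' rotations under the ordering a < a' < b < b'.
#'
#' @param tokens character vector of 4 arm-state tokens.
#' @return list with `label` (concatenated canonical tokens), `tokens`
#'   (canonical order) and `rotation` (offset applied, 0-3).
#' @export
canonicalize_states <- function(tokens) {
  if (length(tokens) != 4L) stop("exactly 4 arm states required", call. = FALSE)
  ranks <- .state_rank(tokens)
  best <- NULL
  best_rot <- 0L
  for (r in 0:3) {
    idx <- ((seq_len(4L) - 1L + r) %% 4L) + 1L
    cand <- ranks[idx]
    if (is.null(best) ||
        isTRUE(.lex_less(cand, best))) {
      best <- cand
      best_rot <- r
    }
  }
  idx <- ((seq_len(4L) - 1L + best_rot) %% 4L) + 1L
  list(label = paste0(tokens[idx], collapse = ""),
       tokens = tokens[idx], rotation = best_rot)
}

.lex_less <- function(x, y) {
  d <- x - y
  nz <- which(d != 0L)
  length(nz) > 0L && d[nz[1L]] < 0L
}

#' Canonical conformer label of one frame
#'
#' Classifies all four arms with [arm_state()] and canonicalizes the state
#' sequence under cyclic arm rotation.
#'
#' @inheritParams arm_state
#' @return an object of class `ConformerLabel`: list with `label`,
#'   `raw_states` (the 4 `ArmState` records in original arm order) and
#'   `rotation`.
#' @export
complex_label <- function(frame, topo, primed_window = c(60, 120),
                          side_tol = 1e-6) {
  states <- lapply(1:4, function(i) {
    arm_state(frame, topo, i, primed_window = primed_window, side_tol = side_tol)
  })
  canon <- canonicalize_states(vapply(states, `[[`, character(1), "token"))
  structure(list(label = canon$label, raw_states = states,
                 rotation = canon$rotation),
            class = "ConformerLabel")
}

#' @export
print.ConformerLabel <- function(x, ...) {
  cat(sprintf("<ConformerLabel: %s (%s)>\n", x$label, format_label(x$label)))
  invisible(x)
}

#' Conformer population table over a trajectory
#'
#' Classifies every frame and tabulates canonical-label fractions over the
#' classifiable frames. Frames with degenerate geometry (undefined torsion,
#' imide centroid on the midplane, zero-length Rh-Rh axis) are excluded and
#' reported through `exclusion_fraction`.
#'
#' @param traj a `Trajectory`.
#' @param topo a `TopologyMap`; unresolved torsion references are taken from
#'   the first frame.
#' @inheritParams arm_state
#' @return an object of class `PopulationTable`: list with `fractions`
#'   (named, sorted decreasing, summing to 1 over included frames),
#'   `n_frames` (included), `n_total`, `exclusion_fraction` and `labels`
#'   (per-frame label, `NA` where excluded).
#' @export
population_table <- function(traj, topo, primed_window = c(60, 120),
                             side_tol = 1e-6) {
  topo <- resolve_theta_ref(topo, traj)
  labels <- vapply(traj$frames, function(fr) {
    tryCatch(
      complex_label(fr, topo, primed_window = primed_window,
                    side_tol = side_tol)$label,
      error = function(e) NA_character_
    )
  }, character(1))
  ok <- !is.na(labels)
  if (!any(ok)) stop("no classifiable frames in trajectory", call. = FALSE)
  tab <- table(labels[ok])
  fractions <- sort(as.numeric(tab) / sum(ok), decreasing = TRUE)
  names(fractions) <- names(sort(tab, decreasing = TRUE))
  structure(
    list(fractions = fractions, n_frames = sum(ok),
         n_total = length(labels),
         exclusion_fraction = mean(!ok), labels = labels),
    class = "PopulationTable"
  )
}

#' @export
print.PopulationTable <- function(x, ...) {
  cat(sprintf("<PopulationTable: %d frames (%.1f%% excluded)>\n",
              x$n_frames, 100 * x$exclusion_fraction))
  top <- utils::head(x$fractions, 8L)
  for (i in seq_along(top)) {
    cat(sprintf("  %-8s %s  %6.3f\n", names(top)[i],
                format_label(names(top)[i]), top[i]))
  }
  invisible(x)
}

#' Flexibility metrics of a conformer population
#'
#' Summarises how spread out a population is: number of distinct states
#' visited, Shannon entropy in bits over the label fractions, and the
#' largest single fraction. A rigid single-conformer ensemble gives entropy
#' 0 and max fraction 1; four equally populated states give 2 bits.
#'
#' @param pop a `PopulationTable`.
#' @return list with `n_states_visited`, `shannon_entropy_bits`,
#'   `max_fraction`.
#' @export
flexibility_metrics <- function(pop) {
  f <- pop$fractions[pop$fractions > 0]
  list(
    n_states_visited = length(f),
    shannon_entropy_bits = -sum(f * log2(f)),
    max_fraction = max(f)
  )
}

#' Per-frame conformer labels as a data frame
#'
#' Convenience export: frame index, canonical label and the four raw
#' torsions, one row per frame (excluded frames carry `NA`).
#'
#' @inheritParams population_table
#' @return data frame with columns `frame`, `label`, `theta_1`..`theta_4`.
#' @export
label_series <- function(traj, topo, primed_window = c(60, 120),
                         side_tol = 1e-6) {
  topo <- resolve_theta_ref(topo, traj)
  rows <- lapply(seq_along(traj$frames), function(k) {
    fr <- traj$frames[[k]]
    res <- tryCatch(
      complex_label(fr, topo, primed_window = primed_window,
                    side_tol = side_tol),
      error = function(e) NULL
    )
    if (is.null(res)) {
      data.frame(frame = fr$frame_index, label = NA_character_,
                 theta_1 = NA_real_, theta_2 = NA_real_,
                 theta_3 = NA_real_, theta_4 = NA_real_)
    } else {
      th <- vapply(res$raw_states, `[[`, numeric(1), "theta_deg")
      data.frame(frame = fr$frame_index, label = res$label,
                 theta_1 = th[1L], theta_2 = th[2L],
                 theta_3 = th[3L], theta_4 = th[4L])
    }
  })
  do.call(rbind, rows)
}
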