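#' Construct a single structure frame
#'
#' A `Frame` holds the ordered atoms of one snapshot of a conformational
#' ensemble: element symbols plus Cartesian coordinates in Angstrom.
#'
#' @param elements character vector of element symbols (non-empty).
#' @param xyz numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @param frame_index integer frame number (>= 0); 0-based position in the
#'   source trajectory by convention.
#' @param comment free-text metadata (e.g. the XYZ comment line).
#' @return an object of class `Frame`.
#' @export
new_frame <- function(elements, xyz, frame_index = 0L, comment = "") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns", call. = FALSE)
  if (length(elements) != nrow(xyz)) {
    stop("length(elements) must equal nrow(xyz)", call. = FALSE)
  }
  if (!all(nzchar(elements))) stop("element symbols must be non-empty", call. = FALSE)
  if (!all(is.finite(xyz))) stop("all coordinates must be finite", call. = FALSE)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(
    list(elements = as.character(elements), xyz = xyz,
         frame_index = as.integer(frame_index), comment = as.character(comment)),
    class = "Frame"
  )
}

#' Construct a trajectory from a list of frames
#'
#' @param frames list of [new_frame()] objects (>= 1), uniform in atom count
#'   and element ordering.
#' @param source free-text provenance string.
#' @return an object of class `Trajectory`.
#' @export
trajectory <- function(frames, source = "") {
  if (length(frames) < 1L) stop("a trajectory needs at least one frame", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "Frame"))) {
    stop("all elements of `frames` must be Frame objects", call. = FALSE)
  }
  ele <- frames[[1L]]$elements
  for (i in seq_along(frames)) {
    if (length(frames[[i]]$elements) != length(ele)) {
      stop(sprintf("frame %d has %d atoms; expected %d", i,
                   length(frames[[i]]$elements), length(ele)), call. = FALSE)
    }
    if (!identical(frames[[i]]$elements, ele)) {
      stop(sprintf("frame %d has a different element ordering than frame 1", i),
           call. = FALSE)
    }
  }
  structure(list(frames = frames, source = as.character(source)),
            class = "Trajectory")
}

#' Number of atoms per frame of a trajectory or frame
#' @param x a `Trajectory` or `Frame`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$frames[[1L]]
  length(x$elements)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' @export
print.Frame <- function(x, ...) {
  cat(sprintf("<Frame %d: %d atoms>\n", x$frame_index, length(x$elements)))
  invisible(x)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory: %d frames x %d atoms>\n", n_frames(x), n_atoms(x)))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Read a multi-frame structure file
#'
#' Reads either a multi-frame (concatenated-block) XYZ file or a multi-model
#' PDB file into a [trajectory()]. Format auto-detection first looks at the
#' file extension and then sniffs the content (a leading bare integer means
#' XYZ; `MODEL`/`ATOM` records mean PDB).
#'
#' @param path path to the structure file.
#' @param format one of `"auto"`, `"pdb"`, `"xyz"`.
#' @return a `Trajectory`; frames are kept in file order.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .sniff_format(path)
  traj <- switch(format, xyz = .read_xyz(path), pdb = .read_pdb(path))
  traj$source <- path
  traj
}

.sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "xyz") return("xyz")
  head <- readLines(path, n = 50L, warn = FALSE)
  head <- head[nzchar(trimws(head))]
  if (length(head) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("^\\s*[0-9]+\\s*$", head[1L])) return("xyz")
  if (any(grepl("^(MODEL|ATOM|HETATM)", head))) return("pdb")
  stop("cannot determine trajectory format of ", path, call. = FALSE)
}

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # trailing blank lines are tolerated
  last <- length(lines)
  while (last > 0L && !nzchar(trimws(lines[last]))) last <- last - 1L
  lines <- lines[seq_len(last)]
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop(sprintf("cannot parse atom count at line %d of %s", i, path),
           call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop(sprintf("truncated XYZ frame %d in %s", fidx + 1L, path), call. = FALSE)
    }
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad) > 0L) {
      stop(sprintf("unparseable coordinate line %d in %s", i + 1L + bad[1L], path),
           call. = FALSE)
    }
    ele <- vapply(toks, `[[`, character(1), 1L)
    xyz <- matrix(suppressWarnings(
      as.numeric(unlist(lapply(toks, function(t) t[2:4])))),
      ncol = 3L, byrow = TRUE)
    if (anyNA(xyz)) {
      bad <- which(apply(is.na(xyz), 1L, any))[1L]
      stop(sprintf("unparseable coordinate line %d in %s", i + 1L + bad, path),
           call. = FALSE)
    }
    frames[[fidx + 1L]] <- new_frame(ele, xyz, frame_index = fidx, comment = comment)
    fidx <- fidx + 1L
    i <- i + 2L + nat
  }
  if (length(frames) > 1L) {
    n1 <- length(frames[[1L]]$elements)
    for (k in seq_along(frames)) {
      if (length(frames[[k]]$elements) != n1) {
        stop(sprintf("frame %d has %d atoms; expected %d (inconsistent XYZ file)",
                     k, length(frames[[k]]$elements), n1), call. = FALSE)
      }
    }
  }
  trajectory(frames)
}

# multi-model PDB via bio3d; occupancy/altloc ignored, element from the
# element column when present, else derived from the atom name
.read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  ele <- pdb$atom$elesy
  if (is.null(ele) || anyNA(ele) || any(!nzchar(trimws(ele)))) {
    fallback <- .element_from_name(pdb$atom$elety)
    if (is.null(ele)) ele <- fallback
    miss <- is.na(ele) | !nzchar(trimws(ele))
    ele[miss] <- fallback[miss]
  }
  ele <- trimws(ele)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(k) {
    new_frame(ele, matrix(xyz[k, ], ncol = 3L, byrow = TRUE), frame_index = k - 1L)
  })
  trajectory(frames)
}

.element_from_name <- function(name) {
  two_letter <- c("Cl", "Br", "Rh", "Si", "Se", "Fe", "Zn", "Cu", "Ni", "Mg",
                  "Na", "Ca", "Mn", "Ru", "Ir", "Pd", "Pt")
  name <- trimws(name)
  stripped <- gsub("[^A-Za-z]", "", name)
  vapply(stripped, function(s) {
    if (nchar(s) >= 2L) {
      cand <- paste0(toupper(substr(s, 1L, 1L)), tolower(substr(s, 2L, 2L)))
      if (cand %in% two_letter) return(cand)
    }
    toupper(substr(s, 1L, 1L))
  }, character(1), USE.NAMES = FALSE)
}

#' Write a trajectory as a multi-frame XYZ file
#'
#' @param traj a `Trajectory`.
#' @param path output file path.
#' @param digits number of decimal places for coordinates (default 8).
#' @return invisibly, `path`.
#' @export
write_xyz <- function(traj, path, digits = 8L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- sprintf("%%-3s %%16.%df %%16.%df %%16.%df", digits, digits, digits)
  for (fr in traj$frames) {
    writeLines(as.character(length(fr$elements)), con)
    writeLines(if (nzchar(fr$comment)) fr$comment else
      sprintf("frame %d", fr$frame_index), con)
    writeLines(sprintf(fmt, fr$elements, fr$xyz[, 1L], fr$xyz[, 2L], fr$xyz[, 3L]),
               con)
  }
  invisible(path)
}

#' Read a topology map from JSON
#'
#' The topology map binds atom indices (1-based, in file order) to the roles
#' of the paddlewheel-carbene model: the two Rh atoms, the carbene carbon and
#' its ester/aryl substituents, and for each of the four carboxylate arms the
#' carboxylate and alpha carbons, the four atoms of the torsion used for the
#' rotational state, the blocking-group ring, and the full imide moiety.
#'
#' @param path path to a JSON file.
#' @return an object of class `TopologyMap`. Arms missing `theta_ref_deg`
#'   carry `NA` and are resolved from the first frame at analysis time (see
#'   [resolve_theta_ref()]).
#' @export
read_topology_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  as_topology_map(raw)
}

#' Build and validate a topology map from a list
#'
#' @param x a named list with fields `rh_carbene_idx`, `rh_distal_idx`,
#'   `carbene_c_idx`, `ester_c_idx`, `aryl_ring_idx` and `arms` (a list of
#'   exactly 4 arm records).
#' @return a validated `TopologyMap`.
#' @export
as_topology_map <- function(x) {
  req <- c("rh_carbene_idx", "rh_distal_idx", "carbene_c_idx", "ester_c_idx",
           "aryl_ring_idx", "arms")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L) {
    stop("topology map missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(x$arms) != 4L) stop("exactly 4 arms required", call. = FALSE)
  scalar_idx <- function(v, nm) {
    v <- as.integer(v)
    if (length(v) != 1L || is.na(v) || v < 1L) {
      stop("invalid index for ", nm, call. = FALSE)
    }
    v
  }
  vec_idx <- function(v, nm, min_len = 1L) {
    v <- as.integer(unlist(v))
    if (length(v) < min_len || anyNA(v) || any(v < 1L)) {
      stop("invalid index vector for ", nm, call. = FALSE)
    }
    v
  }
  topo <- list(
    rh_carbene_idx = scalar_idx(x$rh_carbene_idx, "rh_carbene_idx"),
    rh_distal_idx  = scalar_idx(x$rh_distal_idx, "rh_distal_idx"),
    carbene_c_idx  = scalar_idx(x$carbene_c_idx, "carbene_c_idx"),
    ester_c_idx    = scalar_idx(x$ester_c_idx, "ester_c_idx"),
    aryl_ring_idx  = vec_idx(x$aryl_ring_idx, "aryl_ring_idx", 5L)
  )
  arm_req <- c("carboxylate_c_idx", "alpha_c_idx", "dihedral_quad",
               "blocking_ring_idx", "imide_group_idx")
  topo$arms <- lapply(seq_along(x$arms), function(i) {
    a <- x$arms[[i]]
    miss <- setdiff(arm_req, names(a))
    if (length(miss) > 0L) {
      stop(sprintf("arm %d missing field(s): %s", i, paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    quad <- vec_idx(a$dihedral_quad, sprintf("arm %d dihedral_quad", i), 4L)
    if (length(quad) != 4L) {
      stop(sprintf("arm %d dihedral_quad must have 4 indices", i), call. = FALSE)
    }
    cc <- scalar_idx(a$carboxylate_c_idx, sprintf("arm %d carboxylate_c_idx", i))
    ac <- scalar_idx(a$alpha_c_idx, sprintf("arm %d alpha_c_idx", i))
    if (quad[2L] != cc || quad[3L] != ac) {
      stop(sprintf(
        "arm %d dihedral_quad middle pair must be (carboxylate_c_idx, alpha_c_idx)",
        i), call. = FALSE)
    }
    list(
      carboxylate_c_idx = cc,
      alpha_c_idx = ac,
      dihedral_quad = quad,
      blocking_ring_idx = vec_idx(a$blocking_ring_idx,
                                  sprintf("arm %d blocking_ring_idx", i), 5L),
      imide_group_idx = vec_idx(a$imide_group_idx,
                                sprintf("arm %d imide_group_idx", i), 1L),
      theta_ref_deg = if (is.null(a$theta_ref_deg)) NA_real_ else
        as.numeric(a$theta_ref_deg)
    )
  })
  class(topo) <- "TopologyMap"
  topo
}

#' Check a topology map against a frame or trajectory
#'
#' Verifies that every annotated atom index is in range for the structure.
#'
#' @param topo a `TopologyMap`.
#' @param x a `Frame` or `Trajectory`.
#' @return invisibly, `topo`; raises an error on out-of-range indices.
#' @export
validate_topology <- function(topo, x) {
  stopifnot(inherits(topo, "TopologyMap"))
  nat <- n_atoms(x)
  idx <- .all_topo_indices(topo)
  bad <- idx[idx > nat]
  if (length(bad) > 0L) {
    stop(sprintf("topology index %d out of range (structure has %d atoms)",
                 bad[1L], nat), call. = FALSE)
  }
  invisible(topo)
}

.all_topo_indices <- function(topo) {
  c(topo$rh_carbene_idx, topo$rh_distal_idx, topo$carbene_c_idx,
    topo$ester_c_idx, topo$aryl_ring_idx,
    unlist(lapply(topo$arms, function(a) {
      c(a$carboxylate_c_idx, a$alpha_c_idx, a$dihedral_quad,
        a$blocking_ring_idx, a$imide_group_idx)
    })))
}

#' @export
print.TopologyMap <- function(x, ...) {
  refs <- vapply(x$arms, function(a) a$theta_ref_deg, numeric(1))
  cat(sprintf("<TopologyMap: 4 arms; Rh %d/%d; carbene C %d; theta_ref %s>\n",
              x$rh_carbene_idx, x$rh_distal_idx, x$carbene_c_idx,
              if (anyNA(refs)) "from first frame" else
                paste(sprintf("%.1f", refs), collapse = "/")))
  invisible(x)
}

#' Write a topology map to JSON
#' @param topo a `TopologyMap`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_topology_map <- function(topo, path) {
  out <- unclass(topo)
  out$arms <- lapply(out$arms, function(a) {
    if (is.na(a$theta_ref_deg)) a$theta_ref_deg <- NULL
    a
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Write tabular results to CSV or JSON
#'
#' CSV output keeps full double precision; JSON output serialises a data
#' frame as an array of row objects, and a named list/vector (e.g. a
#' label-to-fraction map) as a JSON object.
#'
#' @param records a data frame, or a named list/vector for JSON.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(records)) records <- as.data.frame(records)
    utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  } else {
    if (is.data.frame(records)) {
      jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = TRUE,
                           digits = 10, pretty = TRUE, na = "null")
    } else {
      jsonlite::write_json(as.list(records), path, auto_unbox = TRUE,
                           digits = 10, pretty = TRUE, na = "null")
    }
  }
  invisible(path)
}
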