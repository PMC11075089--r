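# The conformational coordinate R_c and related loop geometry.
#
# R_c summarizes where the M20 loop "nose" sits relative to the two
# binding-site anchors: P1 (coenzyme side, Calpha centroid of R44/H45/
# G97/R98) and P2 (substrate side, Calpha centroid of 28-LAWF-31). For each
# loop point p -- the turn point j (Calpha centroid of E17/N18) and the
# side-chain centers of the tracked residues E17, N18, M20, P21 -- the
# signed preference d(P2->p) - d(P1->p) is positive when p lies closer to
# the coenzyme anchor. R_c is the mean of these preferences, so closed
# loops (over the coenzyme site) score high (~6-7 A), occluded loops
# (toward the substrate site) score low (< 2 A, possibly negative), and
# open loops fall in between.

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Anchor and tracked-residue definition for the M20 loop coordinate
#'
#' Residue numbers follow the author numbering of the deposited ecDHFR
#' entries. `p1` are the coenzyme-side anchor residues (Calpha), `p2` the
#' substrate-side anchor residues (Calpha), `turn` the loop-turn residues
#' whose Calpha mean is point j, and `tracked` the loop residues whose
#' side-chain heavy-atom centers enter the coordinate.
#'
#' @param p1,p2,turn,tracked Integer residue numbers.
#' @return A list of class `anchor_set`.
#' @export
anchor_set <- function(p1 = c(44L, 45L, 97L, 98L),
                       p2 = 28:31,
                       turn = c(17L, 18L),
                       tracked = c(17L, 18L, 20L, 21L)) {
  structure(list(p1 = as.integer(p1), p2 = as.integer(p2),
                 turn = as.integer(turn), tracked = as.integer(tracked)),
            class = "anchor_set")
}

# Row indices of Calpha atoms for the given residues; error when one is
# missing.
ca_indices <- function(atoms, resnos, what) {
  idx <- lapply(resnos, function(r) {
    which(atoms$resno == r & atoms$name == "CA")
  })
  miss <- resnos[vapply(idx, length, 0L) == 0]
  if (length(miss)) {
    abort(paste0("Missing Calpha atom(s) for ", what, " residue(s): ",
                 paste(miss, collapse = ", ")))
  }
  vapply(idx, `[`, 0L, 1L)
}

# Row indices of side-chain heavy atoms of one residue (may be empty).
sidechain_indices <- function(atoms, resno) {
  which(atoms$resno == resno &
          !(atoms$name %in% .BACKBONE) &
          !(toupper(substr(ifelse(is.na(atoms$element) | atoms$element == "",
                                  substr(atoms$name, 1, 1), atoms$element),
                           1, 1)) == "H"))
}

# Per-frame centroid of a set of template atoms: n_frames x 3 matrix.
centroid_xyz <- function(xyz, idx) {
  cbind(rowMeans(xyz[, 3 * idx - 2, drop = FALSE]),
        rowMeans(xyz[, 3 * idx - 1, drop = FALSE]),
        rowMeans(xyz[, 3 * idx, drop = FALSE]))
}

dist_xyz <- function(a, b) sqrt(rowSums((a - b)^2))

atoms_to_frames <- function(atoms) {
  loop_frames(atoms, matrix(as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
                            nrow = 1))
}

#' Anchor points of a structure
#'
#' Resolves the anchor set on one structure: P1 and P2 (Calpha centroids of
#' the coenzyme- and substrate-side anchors), the loop-turn point j, and the
#' side-chain heavy-atom center of each tracked residue. A tracked residue
#' with no side-chain heavy atoms present (disordered side chain) is dropped
#' from the coordinate with a warning.
#'
#' @param atoms Atom table (see [read_structure()]).
#' @param anchors An [anchor_set()].
#' @return A list with elements `P1`, `P2`, `j` (length-3 numeric),
#'   `i_centers` (named list per tracked residue) and `dropped` (residue
#'   numbers excluded for missing side chains).
#' @export
anchor_points <- function(atoms, anchors = anchor_set()) {
  fr <- atoms_to_frames(atoms)
  sel <- resolve_anchors(fr$atoms, anchors)
  p1 <- drop(centroid_xyz(fr$xyz, sel$p1))
  p2 <- drop(centroid_xyz(fr$xyz, sel$p2))
  j <- drop(centroid_xyz(fr$xyz, sel$turn))
  ic <- lapply(sel$tracked, function(idx) drop(centroid_xyz(fr$xyz, idx)))
  list(P1 = p1, P2 = p2, j = j, i_centers = ic, dropped = sel$dropped)
}

# Resolve all index sets once per topology; warns about dropped residues.
resolve_anchors <- function(atoms, anchors) {
  p1 <- ca_indices(atoms, anchors$p1, "P1 anchor")
  p2 <- ca_indices(atoms, anchors$p2, "P2 anchor")
  turn <- ca_indices(atoms, anchors$turn, "loop-turn")
  tracked <- lapply(anchors$tracked, function(r) sidechain_indices(atoms, r))
  names(tracked) <- paste0("res", anchors$tracked)
  empty <- vapply(tracked, length, 0L) == 0
  dropped <- anchors$tracked[empty]
  if (length(dropped)) {
    warn(paste0("Tracked residue(s) without side-chain heavy atoms dropped ",
                "from R_c: ", paste(dropped, collapse = ", ")))
  }
  list(p1 = p1, p2 = p2, turn = turn,
       tracked = tracked[!empty], dropped = dropped)
}

# Shared engine: per-frame loop descriptors for a loop_frames object.
descriptors_from_frames <- function(frames, anchors = anchor_set(),
                                    boundaries = class_boundaries()) {
  atoms <- frames$atoms
  xyz <- frames$xyz
  sel <- resolve_anchors(atoms, anchors)
  P1 <- centroid_xyz(xyz, sel$p1)
  P2 <- centroid_xyz(xyz, sel$p2)
  J <- centroid_xyz(xyz, sel$turn)
  d_p1j <- dist_xyz(P1, J)
  d_p2j <- dist_xyz(P2, J)
  pref <- d_p2j - d_p1j
  out <- tibble(frame = seq_len(nrow(xyz)), Rc = NA_real_,
                dP1j = d_p1j, dP2j = d_p2j)
  acc <- pref
  for (nm in names(sel$tracked)) {
    Ci <- centroid_xyz(xyz, sel$tracked[[nm]])
    d1 <- dist_xyz(P1, Ci)
    d2 <- dist_xyz(P2, Ci)
    out[[paste0("dP1_", nm)]] <- d1
    out[[paste0("dP2_", nm)]] <- d2
    acc <- acc + (d2 - d1)
  }
  out$Rc <- acc / (1 + length(sel$tracked))
  # marker distances (reported when the marker Calphas are present)
  mark <- function(r1, r2) {
    i1 <- which(atoms$resno == r1 & atoms$name == "CA")
    i2 <- which(atoms$resno == r2 & atoms$name == "CA")
    if (length(i1) && length(i2)) {
      dist_xyz(centroid_xyz(xyz, i1[1]), centroid_xyz(xyz, i2[1]))
    } else {
      rep(NA_real_, nrow(xyz))
    }
  }
  out$dN18_H45 <- mark(18L, 45L)
  out$dE17_L28 <- mark(17L, 28L)
  out$class <- classify_conformer(out$Rc, boundaries)
  out
}

#' Loop descriptor of a single structure
#'
#' Computes the conformational coordinate R_c of one structure together
#' with its constituent distances (P1/P2 to the turn point j and to each
#' tracked side-chain center) and the two marker distances
#' Calpha(N18)-Calpha(H45) and Calpha(E17)-Calpha(L28). R_c is invariant
#' under rigid-body motion of all coordinates.
#'
#' @param atoms Atom table (see [read_structure()]).
#' @param anchors An [anchor_set()].
#' @param boundaries Class boundaries, see [class_boundaries()].
#' @return A one-row tibble: `Rc`, `dP1j`, `dP2j`, per-residue `dP1_res*`
#'   and `dP2_res*`, `dN18_H45`, `dE17_L28`, `class`.
#' @export
compute_rc <- function(atoms, anchors = anchor_set(),
                       boundaries = class_boundaries()) {
  out <- descriptors_from_frames(atoms_to_frames(atoms), anchors, boundaries)
  out$frame <- NULL
  out
}

#' R_c time series over a trajectory
#'
#' Applies [compute_rc()] to every retained frame of a trajectory, fully
#' vectorized over frames.
#'
#' @param frames A [loop_frames()] object.
#' @param anchors An [anchor_set()].
#' @param stride Keep every `stride`-th frame (default 1).
#' @param boundaries Class boundaries, see [class_boundaries()].
#' @return A tibble with one row per retained frame; `frame` holds the
#'   original frame index.
#' @export
rc_timeseries <- function(frames, anchors = anchor_set(), stride = 1,
                          boundaries = class_boundaries()) {
  if (!inherits(frames, "loop_frames")) abort("`frames` must be a loop_frames object.")
  keep <- seq(1, n_frames(frames), by = stride)
  sub <- loop_frames(frames$atoms, frames$xyz[keep, , drop = FALSE])
  out <- descriptors_from_frames(sub, anchors, boundaries)
  out$frame <- keep
  out
}

#' Default R_c class boundaries
#'
#' Upper R_c bounds (Angstrom) of the occluded and intermediate classes and
#' the lower bound of the closed class: occluded `Rc < occluded`,
#' intermediate `occluded <= Rc < intermediate`, open
#' `intermediate <= Rc < closed`, closed `Rc >= closed`. The default closed
#' boundary 5.75 A is the midpoint of the gap between the crystallographic
#' open (4.6-5.7 A) and closed (5.8-7.4 A) ranges.
#'
#' @param occluded,intermediate,closed Boundary values in Angstrom.
#' @return A named numeric vector.
#' @export
class_boundaries <- function(occluded = 2.0, intermediate = 4.0,
                             closed = 5.75) {
  if (!(occluded <= intermediate && intermediate <= closed)) {
    abort("Boundaries must be ordered: occluded <= intermediate <= closed.")
  }
  c(occluded = occluded, intermediate = intermediate, closed = closed)
}

#' Classify an M20-loop conformer from R_c
#'
#' Total, piecewise-constant mapping of finite R_c values onto the
#' conformer classes occluded, intermediate, open, closed.
#'
#' @param Rc Numeric vector of R_c values (Angstrom).
#' @param boundaries See [class_boundaries()].
#' @return Character vector of class labels (NA for non-finite input).
#' @examples
#' classify_conformer(c(1.0, 3.0, 5.0, 6.5))
#' @export
classify_conformer <- function(Rc, boundaries = class_boundaries()) {
  b <- boundaries
  dplyr::case_when(
    !is.finite(Rc) ~ NA_character_,
    Rc < b[["occluded"]] ~ "occluded",
    Rc < b[["intermediate"]] ~ "intermediate",
    Rc < b[["closed"]] ~ "open",
    TRUE ~ "closed"
  )
}

#' The reaction plane of the active site
#'
#' Plane through the three Calpha-group centroids that bracket the
#' hydride-transfer geometry: the B-helix 28-LAWF-31 group, the C-helix
#' R44/H45 group, and the F-helix G97/R98 group. The unit normal is
#' oriented toward the M20-loop side (positive signed distance for the
#' loop-turn point j when it can be resolved).
#'
#' @param atoms Atom table.
#' @return A list of class `reaction_plane`: `point` (on the plane),
#'   `normal` (unit), `centroids` (3 x 3 matrix, one row per group).
#' @export
reaction_plane <- function(atoms) {
  fr <- atoms_to_frames(atoms)
  g <- list(b_helix = 28:31, c_helix = c(44L, 45L), f_helix = c(97L, 98L))
  cent <- t(vapply(g, function(r) {
    drop(centroid_xyz(fr$xyz, ca_indices(fr$atoms, r, "reaction-plane")))
  }, numeric(3)))
  v1 <- cent[2, ] - cent[1, ]
  v2 <- cent[3, ] - cent[1, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  len <- sqrt(sum(nrm^2))
  if (len < 1e-9 * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2)))) {
    abort("Reaction-plane centroids are collinear; plane undefined.")
  }
  nrm <- nrm / len
  turn <- try(drop(centroid_xyz(fr$xyz,
                                ca_indices(fr$atoms, c(17L, 18L), "loop-turn"))),
              silent = TRUE)
  if (!inherits(turn, "try-error")) {
    if (sum((turn - cent[1, ]) * nrm) < 0) nrm <- -nrm
  }
  structure(list(point = cent[1, ], normal = nrm, centroids = cent),
            class = "reaction_plane")
}

#' Signed distance from the reaction plane
#'
#' @param plane A [reaction_plane()].
#' @param p Length-3 point or n x 3 matrix.
#' @return Signed distance(s), positive on the M20-loop side.
#' @export
plane_distance <- function(plane, p) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  drop(sweep(p, 2, plane$point) %*% plane$normal)
}
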