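# Shared fixtures built in code.

frame_atoms_for_test <- function(fr, i) loopstate:::frame_atoms(fr, i)

# A deterministic proper rotation matrix from a seed.
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply a rigid-body motion (rotation R then translation v) to an atom table.
rigid_move <- function(atoms, R, v) {
  m <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- m[, 1] + v[1]
  atoms$y <- m[, 2] + v[2]
  atoms$z <- m[, 3] + v[3]
  atoms
}

# Tiny hand-checkable structure: anchor Calphas on a simple lattice.
# P1 centroid (0,0,0); P2 centroid (10,0,0); turn Calphas straddling
# (4,3,0) so j = (4,3,0); one side-chain atom per tracked residue at the
# positions given.
toy_hand_structure <- function(side_positions = list(
                                 res17 = c(3, 3, 1), res18 = c(5, 3, -1),
                                 res20 = c(4, 4, 0), res21 = c(4, 2, 0))) {
  ca <- function(resno, resname, p) {
    tibble::tibble(name = "CA", resname = resname, resno = resno,
                   chain = "A", element = "C", insert = "", alt = "",
                   x = p[1], y = p[2], z = p[3])
  }
  sc <- function(resno, resname, name, p) {
    tibble::tibble(name = name, resname = resname, resno = resno,
                   chain = "A", element = substr(name, 1, 1), insert = "",
                   alt = "", x = p[1], y = p[2], z = p[3])
  }
  dplyr::bind_rows(
    ca(44L, "ARG", c(1, 1, 0)), ca(45L, "HIS", c(-1, -1, 0)),
    ca(97L, "GLY", c(1, -1, 0)), ca(98L, "ARG", c(-1, 1, 0)),
    ca(28L, "LEU", c(11, 1, 0)), ca(29L, "ALA", c(9, -1, 0)),
    ca(30L, "TRP", c(11, -1, 0)), ca(31L, "PHE", c(9, 1, 0)),
    ca(17L, "GLU", c(4, 3, 1)), ca(18L, "ASN", c(4, 3, -1)),
    sc(17L, "GLU", "CD", side_positions$res17),
    sc(18L, "ASN", "CG", side_positions$res18),
    sc(20L, "MET", "SD", side_positions$res20),
    sc(21L, "PRO", "CG", side_positions$res21)
  )
}

# Hand evaluation of the coordinate on the toy structure above.
hand_rc <- function(side_positions = list(
                      res17 = c(3, 3, 1), res18 = c(5, 3, -1),
                      res20 = c(4, 4, 0), res21 = c(4, 2, 0))) {
  p1 <- c(0, 0, 0); p2 <- c(10, 0, 0); j <- c(4, 3, 0)
  d <- function(a, b) sqrt(sum((a - b)^2))
  pts <- c(list(j = j), side_positions)
  mean(vapply(pts, function(p) d(p2, p) - d(p1, p), 0))
}
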