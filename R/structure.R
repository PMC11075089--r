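# Structure and trajectory I/O. PDB parsing/writing is delegated to bio3d;
# the plain-text frame dialect (one `label x y z` line per atom, frames
# separated by END) is this package's own fixture format.

#' Read a PDB structure into an atom table
#'
#' Parses a PDB file with bio3d and returns a tidy atom table for one chain
#' and one MODEL. Alternate locations are resolved by policy (default: keep
#' blank or 'A'); hydrogens are retained but ignored by heavy-atom
#' selections downstream.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; default the first chain containing protein
#'   (ATOM) records.
#' @param model MODEL number to keep (default 1, the first).
#' @param altloc Alternate-location codes to keep (default blank and "A").
#' @return A tibble with columns `name`, `element`, `resname`, `resno`,
#'   `insert`, `chain`, `alt`, `x`, `y`, `z` (Angstrom) and `type`
#'   (ATOM/HETATM).
#' @export
read_structure <- function(path, chain = NULL, model = 1,
                           altloc = c("", "A")) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model > n_models) abort(paste0("MODEL ", model, " not present (file has ",
                                     n_models, ")."))
  if (model > 1) {
    m <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
  }
  atoms <- tibble(
    type = at$type,
    name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy),
    resname = at$resid,
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    chain = ifelse(is.na(at$chain), "", at$chain),
    alt = ifelse(is.na(at$alt), "", at$alt),
    x = at$x, y = at$y, z = at$z
  )
  if (is.null(chain)) {
    prot <- atoms$chain[atoms$type == "ATOM"]
    chain <- if (length(prot)) prot[1] else atoms$chain[1]
  }
  if (!chain %in% atoms$chain) {
    abort(paste0("Chain '", chain, "' not found in ", path))
  }
  atoms <- atoms[atoms$chain == chain & atoms$alt %in% altloc, , drop = FALSE]
  atoms
}

#' Write an atom table to a PDB file
#'
#' Thin wrapper over [bio3d::write.pdb()]. Atoms with `type == "HETATM"`
#' are written as HETATM records.
#'
#' @param atoms Atom table (see [read_structure()]). A `type` column is
#'   optional (defaults to ATOM).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  n <- nrow(atoms)
  type <- if ("type" %in% names(atoms)) atoms$type else rep("ATOM", n)
  bio3d::write.pdb(
    file = path,
    type = type,
    eleno = seq_len(n),
    elety = atoms$name,
    resid = atoms$resname,
    chain = if ("chain" %in% names(atoms)) atoms$chain else rep("A", n),
    resno = atoms$resno,
    xyz = as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
    elesy = if ("element" %in% names(atoms)) atoms$element else ""
  )
  invisible(path)
}

#' Construct a trajectory (frames) object
#'
#' A `loop_frames` object couples an atom template (identities shared by all
#' frames) with an `n_frames x 3*n_atoms` coordinate matrix in bio3d xyz
#' layout (x1, y1, z1, x2, ...).
#'
#' @param atoms Atom template: tibble with at least `name`, `resname`,
#'   `resno` (coordinates in the template are ignored).
#' @param xyz Numeric matrix, `n_frames` rows, `3*n_atoms` columns.
#' @return An object of class `loop_frames`.
#' @export
loop_frames <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(atoms)) {
    abort("`xyz` must have 3 columns per template atom.")
  }
  structure(list(atoms = as_tibble(atoms), xyz = xyz), class = "loop_frames")
}

#' @export
print.loop_frames <- function(x, ...) {
  cat("<loop_frames> ", nrow(x$xyz), " frames x ", nrow(x$atoms), " atoms\n",
      sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param frames A `loop_frames` object.
#' @return Integer frame count.
#' @export
n_frames <- function(frames) nrow(frames$xyz)

# Atom table for one frame of a loop_frames object.
frame_atoms <- function(frames, i) {
  m <- matrix(frames$xyz[i, ], ncol = 3, byrow = TRUE)
  out <- frames$atoms
  out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
  out
}

# Encode/decode the text-dialect atom label NAME:RESNAME:RESNO.
.frame_label <- function(atoms) {
  paste(atoms$name, atoms$resname, atoms$resno, sep = ":")
}

#' Read trajectory frames
#'
#' Reads MD-style frames into a [loop_frames()] object from: the plain-text
#' frame dialect (`format = "txt"`; one `label x y z` line per atom with
#' label `NAME:RESNAME:RESNO`, frames separated by a line `END`), a
#' multi-MODEL PDB (`format = "pdb"`), or a binary DCD plus a PDB topology
#' (`format = "dcd"`, via [bio3d::read.dcd()]). The format is inferred from
#' the file extension by default.
#'
#' @param path Trajectory file.
#' @param top Path to a PDB topology; required for DCD.
#' @param format One of "auto", "txt", "pdb", "dcd".
#' @param chain Chain passed to [read_structure()] for PDB-based reads.
#' @return A `loop_frames` object.
#' @export
read_frames <- function(path, top = NULL, format = c("auto", "txt", "pdb", "dcd"),
                        chain = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", dcd = "dcd", "txt")
  }
  if (format == "txt") return(read_frames_txt(path))
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    atoms <- read_structure(path, chain = chain)
    if (!is.null(chain) || length(unique(pdb$atom$chain)) > 1) {
      # restrict xyz columns to the selected chain rows
      keep <- which(pdb$atom$chain %in% unique(atoms$chain) &
                      ifelse(is.na(pdb$atom$alt), "", pdb$atom$alt) %in% c("", "A"))
      cols <- as.vector(rbind(3 * (keep - 1) + 1, 3 * (keep - 1) + 2, 3 * keep))
      return(loop_frames(atoms, pdb$xyz[, cols, drop = FALSE]))
    }
    return(loop_frames(atoms, unclass(pdb$xyz)))
  }
  if (is.null(top)) abort("DCD trajectories need a PDB `top`ology.")
  atoms <- read_structure(top, chain = chain)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  loop_frames(atoms, unclass(xyz))
}

read_frames_txt <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  ends <- which(toupper(lines) == "END")
  if (length(ends) == 0) ends <- length(lines) + 1L
  if (tail(ends, 1) <= length(lines) &&
      tail(ends, 1) != length(lines)) {
    # trailing atoms after the last END form a final unterminated frame
    ends <- c(ends, length(lines) + 1L)
  } else if (tail(ends, 1) < length(lines)) {
    ends <- c(ends, length(lines) + 1L)
  }
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- starts < ends
  starts <- starts[keep]; ends <- ends[keep]
  n_fr <- length(starts)
  if (n_fr == 0) abort("No frames found in text trajectory.")
  parse_frame <- function(s, e) {
    fl <- lines[s:(e - 1)]
    parts <- strsplit(fl, "[ \t]+")
    lab <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    list(lab = lab, xyz = xyz)
  }
  first <- parse_frame(starts[1], ends[1])
  n_at <- length(first$lab)
  lab3 <- strsplit(first$lab, ":", fixed = TRUE)
  atoms <- tibble(
    name = vapply(lab3, `[`, "", 1),
    resname = vapply(lab3, function(p) ifelse(length(p) >= 2, p[2], "UNK"), ""),
    resno = vapply(lab3, function(p) {
      v <- suppressWarnings(as.integer(p[3])); ifelse(is.na(v), 0L, v)
    }, 0L),
    chain = "A", element = substr(vapply(lab3, `[`, "", 1), 1, 1),
    insert = "", alt = ""
  )
  xyz <- matrix(NA_real_, nrow = n_fr, ncol = 3 * n_at)
  xyz[1, ] <- as.vector(t(first$xyz))
  if (n_fr > 1) {
    for (i in 2:n_fr) {
      fr <- parse_frame(starts[i], ends[i])
      if (length(fr$lab) != n_at || any(fr$lab != first$lab)) {
        abort(paste0("Frame ", i, " does not match the topology of frame 1."))
      }
      xyz[i, ] <- as.vector(t(fr$xyz))
    }
  }
  loop_frames(atoms, xyz)
}

#' Write trajectory frames in the plain-text dialect
#'
#' @param frames A `loop_frames` object.
#' @param path Output file.
#' @param digits Coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, digits = 6) {
  lab <- .frame_label(frames$atoms)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(n_frames(frames))) {
    m <- matrix(frames$xyz[i, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%s %.*f %.*f %.*f", lab,
                       digits, m[, 1], digits, m[, 2], digits, m[, 3]), con)
    writeLines("END", con)
  }
  invisible(path)
}

#' Download a PDB entry (network, opt-in)
#'
#' Fetches `https://files.rcsb.org/download/<id>.pdb` into `dir`. This is
#' the only network-touching function in the package and is never called by
#' the core analysis path; an existing file in `dir` is reused.
#'
#' @param id 4-character PDB identifier.
#' @param dir Destination directory.
#' @return Path to the downloaded (or cached) file.
#' @export
fetch_pdb <- function(id, dir = tempdir()) {
  id <- tolower(id)
  if (nchar(id) != 4) abort("`id` must be a 4-character PDB code.")
  dest <- file.path(dir, paste0(id, ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- paste0("https://files.rcsb.org/download/", id, ".pdb")
  status <- try(suppressWarnings(download.file(url, dest, quiet = TRUE,
                                               mode = "wb")),
                silent = TRUE)
  if (inherits(status, "try-error") || !identical(status, 0L) ||
      !file.exists(dest) || file.size(dest) == 0) {
    if (file.exists(dest)) unlink(dest)
    abort(paste0("Could not download PDB entry '", id, "' (no network?)."))
  }
  dest
}
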