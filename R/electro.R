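# Distance-dependent electrostatic potentials at a loop reference point.
#
# Phi(R) is the cumulative vacuum Coulomb potential at the reference point
# from all charged particles within radius R (particle summation, minimum
# image, no dielectric), in kcal/(mol*e) with k_C = 332.0637
# kcal*A/(mol*e^2). The RDF-integral route must agree with the particle
# summation on the same frames; the pair of routes pins the semantics.

#' Loop reference point for electrostatic potentials
#'
#' The geometric center of the Calpha atoms of residues E17, N18 and M20
#' (the M20-loop nose), carrying the loop's net charge (default -1 e from
#' the deprotonated E17 carboxylate).
#'
#' @param atoms Atom table, or `NULL` to supply `position` directly.
#' @param residues Residue numbers averaged over (default 17, 18, 20).
#' @param position Length-3 position (Angstrom), used when `atoms` is NULL.
#' @param charge Reference charge q_alpha in units of e (default -1).
#' @return A list of class `reference_point` with `position` and `charge`.
#' @export
reference_point <- function(atoms = NULL, residues = c(17L, 18L, 20L),
                            position = NULL, charge = -1) {
  if (is.null(position)) {
    if (is.null(atoms)) abort("Supply `atoms` or `position`.")
    fr <- atoms_to_frames(atoms)
    position <- drop(centroid_xyz(fr$xyz,
                                  ca_indices(fr$atoms, residues, "reference")))
  }
  if (length(position) != 3 || any(!is.finite(position))) {
    abort("`position` must be a finite length-3 vector.")
  }
  structure(list(position = as.numeric(position), charge = charge),
            class = "reference_point")
}

validate_particles <- function(particles) {
  req <- c("frame", "label", "q", "x", "y", "z")
  if (!is.data.frame(particles) || !all(req %in% names(particles))) {
    abort("`particles` needs columns frame, label, q, x, y, z.")
  }
  invisible(particles)
}

# distances of all particles from the reference, grouped by frame
particle_dists <- function(particles, ref, box_edge) {
  xyz <- as.matrix(particles[, c("x", "y", "z")])
  min_image_dist(ref$position, xyz, box_edge)
}

#' Radial distribution function around the reference point
#'
#' For each species X, `g(r) = <shell count> / (rho_X * shell volume)`,
#' ensemble-averaged over frames with minimum-image distances. For a
#' uniform fluid g(r) tends to 1 at large r.
#'
#' @param particles Particle table: columns `frame`, `label`, `q`, `x`,
#'   `y`, `z` (Angstrom), e.g. from [gen_ionic_config()].
#' @param ref A [reference_point()].
#' @param box_edge Cubic box edge (Angstrom).
#' @param dr Shell width (Angstrom).
#' @param r_max Outer radius; must be at most half the box edge.
#' @param densities Optional tibble `label`, `density` (particles/A^3);
#'   default: mean per-frame count / box volume.
#' @param n_frames Number of frames averaged over; default
#'   `max(particles$frame)` (frames with no particles still count).
#' @return A tibble of class `rdf_profile`: `r` (shell centers), `label`,
#'   `g`, `count` (mean shell count per frame).
#' @export
rdf <- function(particles, ref, box_edge, dr = 0.1, r_max = box_edge / 2,
                densities = NULL, n_frames = NULL) {
  validate_particles(particles)
  if (r_max > box_edge / 2 + 1e-9) {
    abort("`r_max` must be at most half the box edge (minimum image).")
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(particles)) max(particles$frame) else 1L
  }
  nb <- ceiling(r_max / dr - 1e-9)
  edges <- dr * (0:nb)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  vol_shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  labels <- sort(unique(particles$label))
  if (is.null(densities)) {
    densities <- tibble(
      label = labels,
      density = vapply(labels, function(l) {
        sum(particles$label == l) / n_frames / box_edge^3
      }, 0)
    )
  }
  r_all <- particle_dists(particles, ref, box_edge)
  out <- purrr::map_dfr(labels, function(l) {
    rs <- r_all[particles$label == l & r_all < r_max]
    counts <- tabulate(pmin(floor(rs / dr) + 1L, nb), nbins = nb) / n_frames
    rho <- densities$density[densities$label == l]
    g <- if (length(rho) && rho > 0) counts / (rho * vol_shell) else rep(0, nb)
    tibble(r = mids, label = l, g = g, count = counts)
  })
  structure(out, dr = dr, r_max = r_max, box_edge = box_edge,
            densities = densities, n_frames = n_frames,
            class = c("rdf_profile", class(tibble())))
}

new_potential_profile <- function(tbl, dR) {
  structure(as_tibble(tbl), dR = dR,
            class = c("potential_profile", class(tibble())))
}

#' Cumulative electrostatic potential by particle summation
#'
#' `Phi(R)` is the frame-averaged sum of `k_C * q_i / r_i` over all
#' particles within minimum-image distance `r_i <= R` of the reference
#' point: the vacuum Coulomb potential of the ion (or solvent) cloud inside
#' a growing sphere, in kcal/(mol*e). Frames with a particle closer than
#' `reject_within` of the reference are dropped with a warning; a particle
#' exactly at the reference is an error.
#'
#' @inheritParams rdf
#' @param dR Radial grid spacing of the output profile (Angstrom).
#' @param R_max Largest radius reported.
#' @param reject_within Frame-rejection radius around the reference
#'   (default 0.5 Angstrom).
#' @return A tibble of class `potential_profile`: `R`, `phi`
#'   (kcal/(mol*e)), `err` (standard error over frames).
#' @examples
#' p <- tibble::tibble(frame = 1, label = "Na+", q = 1, x = 5, y = 0, z = 0)
#' ref <- reference_point(position = c(0, 0, 0))
#' prof <- phi_particle_sum(p, ref, box_edge = 40, dR = 1, R_max = 10)
#' prof$phi[prof$R >= 5][1] # 332.0637/5 = 66.41
#' @export
phi_particle_sum <- function(particles, ref, box_edge, dR = 0.1,
                             R_max = box_edge / 2, reject_within = 0.5,
                             n_frames = NULL) {
  validate_particles(particles)
  if (R_max > box_edge / 2 + 1e-9) {
    abort("`R_max` must be at most half the box edge (minimum image).")
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(particles)) max(particles$frame) else 1L
  }
  r <- particle_dists(particles, ref, box_edge)
  if (any(r == 0)) abort("A particle sits exactly at the reference point.")
  bad_frames <- unique(particles$frame[r < reject_within])
  if (length(bad_frames)) {
    warn(paste0(length(bad_frames), " frame(s) rejected: particle within ",
                reject_within, " A of the reference point."))
    keep <- !particles$frame %in% bad_frames
    particles <- particles[keep, , drop = FALSE]
    r <- r[keep]
  }
  frames_used <- setdiff(seq_len(n_frames), bad_frames)
  if (!length(frames_used)) abort("All frames rejected.")
  nb <- ceiling(R_max / dR - 1e-9)
  Rgrid <- dR * seq_len(nb)
  inside <- r <= R_max
  contrib <- .kC * particles$q[inside] / r[inside]
  bin <- pmin(ceiling(r[inside] / dR), nb)
  fidx <- match(particles$frame[inside], frames_used)
  # per-frame cumulative profile: sum contributions into (frame, bin) cells
  nf <- length(frames_used)
  cell <- (fidx - 1L) * nb + bin
  inc <- numeric(nf * nb)
  agg <- tapply(contrib, cell, sum)
  inc[as.integer(names(agg))] <- agg
  per_frame <- matrix(inc, nrow = nf, ncol = nb, byrow = TRUE)
  per_frame <- t(apply(per_frame, 1, cumsum))
  if (nf == 1) per_frame <- matrix(per_frame, nrow = 1)
  phi <- colMeans(per_frame)
  err <- if (nf > 1) apply(per_frame, 2, sd) / sqrt(nf) else rep(NA_real_, nb)
  new_potential_profile(tibble(R = Rgrid, phi = phi, err = err), dR)
}

#' Electrostatic potential from radial distribution functions
#'
#' Integral form of the cumulative ion potential:
#' `Phi(R) = sum_X 4 pi rho_X q_X k_C int_0^R r g_X(r) dr`
#' by trapezoidal quadrature on the RDF grid. On identical frames this
#' agrees with [phi_particle_sum()] within quadrature plus sampling error.
#'
#' @param rdf_profile An [rdf()] result.
#' @param charges Tibble `label`, `q` (charge per species, units of e).
#' @param R_max Largest radius reported (default the RDF extent).
#' @return A `potential_profile` tibble (`err` is NA; use the particle
#'   summation for frame-resolved errors).
#' @export
phi_from_rdf <- function(rdf_profile, charges, R_max = NULL) {
  if (!inherits(rdf_profile, "rdf_profile")) abort("`rdf_profile` must come from rdf().")
  dens <- attr(rdf_profile, "densities")
  dr <- attr(rdf_profile, "dr")
  if (is.null(R_max)) R_max <- attr(rdf_profile, "r_max")
  if (R_max > attr(rdf_profile, "r_max") + 1e-9) {
    abort("`R_max` exceeds the RDF grid.")
  }
  labels <- unique(rdf_profile$label)
  mids <- sort(unique(rdf_profile$r))
  mids <- mids[mids <= R_max + dr / 2 + 1e-9]
  nb <- length(mids)
  edges <- mids + dr / 2 # report at shell upper edges, like the particle sum
  total <- numeric(nb)
  for (l in labels) {
    sub <- rdf_profile[rdf_profile$label == l, , drop = FALSE]
    if (!all(abs(sub$r[seq_len(nb)] - mids) < 1e-9)) {
      abort("RDF grids differ between species.")
    }
    q <- charges$q[charges$label == l]
    rho <- dens$density[dens$label == l]
    if (!length(q)) abort(paste0("No charge supplied for species ", l))
    f_mid <- mids * sub$g[seq_len(nb)]
    # integrand values at shell edges by linear interpolation (0 at r = 0)
    f_edge <- c((head(f_mid, -1) + tail(f_mid, -1)) / 2,
                f_mid[nb] + (f_mid[nb] - if (nb > 1) f_mid[nb - 1] else 0) / 2)
    # trapezoid over the refined nodes 0, m1, e1, m2, e2, ...
    lower <- c(0, head(f_edge, -1))
    per_shell <- dr / 4 * (lower + 2 * f_mid + f_edge)
    total <- total + 4 * pi * rho * q * .kC * cumsum(per_shell)
  }
  new_potential_profile(tibble(R = edges, phi = total, err = NA_real_), dr)
}

#' TIP3P water partial charges
#'
#' @return A tibble `name`, `q` with the three-site TIP3P charges
#'   (O -0.834 e, H +0.417 e).
#' @export
tip3p_charges <- function() {
  tibble(name = c("O", "H1", "H2"), q = c(-0.834, 0.417, 0.417))
}

#' Solvent contribution to the electrostatic potential
#'
#' Applies the particle-summation potential to water atoms carrying TIP3P
#' partial charges. Water atoms are identified by the first letter of their
#' `label`/`name` (O or H) when no explicit `q` column is present.
#'
#' @param waters Water atom table: `frame`, `label` (or `name`), `x`, `y`,
#'   `z`, optional `q`.
#' @inheritParams phi_particle_sum
#' @return A `potential_profile` tibble.
#' @export
phi_solvent <- function(waters, ref, box_edge, dR = 0.1,
                        R_max = box_edge / 2, reject_within = 0.5,
                        n_frames = NULL) {
  if (!"label" %in% names(waters) && "name" %in% names(waters)) {
    waters$label <- waters$name
  }
  if (!"q" %in% names(waters)) {
    el <- toupper(substr(waters$label, 1, 1))
    if (!all(el %in% c("O", "H"))) {
      abort("Cannot assign TIP3P charges: atom labels must start with O or H.")
    }
    waters$q <- ifelse(el == "O", -0.834, 0.417)
  }
  phi_particle_sum(waters, ref, box_edge, dR, R_max, reject_within, n_frames)
}

#' Linear free-energy estimate from the total potential
#'
#' Linear-response estimate of the ionic-strength contribution to the loop
#' free energy: half the total electrostatic potential (ions + solvent +
#' protein) at a sufficiently large radius, multiplied by the reference
#' charge: `dG = 1/2 * q_alpha * Phi_total`.
#'
#' @param q_alpha Reference charge in e (default -1).
#' @param phi_total Total potential at large R, kcal/(mol*e).
#' @return Free energy in kcal/mol.
#' @examples
#' lfer_free_energy(-1, 10) # -5
#' @export
lfer_free_energy <- function(q_alpha, phi_total) {
  0.5 * q_alpha * phi_total
}

#' Plot a cumulative potential profile
#'
#' @param object A `potential_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot potential_profile
autoplot.potential_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$R, y = .data$phi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "R (Å)", y = expression(Phi(R) ~ "(kcal/(mol·e))"))
  if (any(is.finite(object$err))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$phi - .data$err, ymax = .data$phi + .data$err),
      alpha = 0.3
    )
  }
  p
}
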