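# Seed-deterministic ground-truth generators: Boltzmann samples of R_c
# from a specified 1-D free-energy profile, embedding of those samples
# into 3-D frames with valid anchor geometry, umbrella-biased Metropolis
# samples, ideal ionic configurations, and toy structures per conformer
# class. They make every analysis stage testable without MD trajectories.

#' Toy free-energy potential
#'
#' Wraps either an analytic function or a tabulated profile as the
#' ground-truth W(Rc) used by the samplers.
#'
#' @param fun Function `W(x)` in kcal/mol, or `NULL` when tabulating.
#' @param grid,W Tabulated profile (monotone grid, finite W); interpolated
#'   with a natural spline.
#' @param domain Length-2 domain of definition (Angstrom).
#' @return A list of class `toy_potential` with `fun` and `domain`.
#' @export
toy_potential <- function(fun = NULL, grid = NULL, W = NULL, domain = NULL) {
  if (is.null(fun)) {
    if (is.null(grid) || is.null(W)) abort("Supply `fun` or `grid` + `W`.")
    if (any(!is.finite(W))) abort("Tabulated W must be finite.")
    fun <- splinefun(grid, W, method = "natural")
    if (is.null(domain)) domain <- range(grid)
  }
  if (is.null(domain)) abort("`domain` is required for analytic potentials.")
  structure(list(fun = fun, domain = as.numeric(domain)),
            class = "toy_potential")
}

#' Analytic double-well potential
#'
#' A C1 double well with exactly controlled geometry, emulating the
#' two-state (occluded vs closed) free-energy profiles: a raised-cosine
#' barrier between a deep well at `well_a` (W = 0) and a shallower well at
#' `well_b` (W = `delta`), with top exactly `delta + barrier`, flanked by
#' harmonic walls. `barrier` is therefore the crossing cost from the
#' shallower well, matching [barrier_height()]'s convention.
#'
#' @param well_a,well_b Well positions (Angstrom). Defaults -0.17 and 6.0,
#'   the occluded and closed minima of the high-ionic-strength profiles.
#' @param barrier Barrier height from the shallower well (kcal/mol).
#' @param delta Depth offset of well b above well a (kcal/mol, >= 0).
#' @param wall_k Curvature of the outer harmonic walls (kcal/(mol*A^2)).
#' @param wall_extent How far beyond the wells the domain extends (A).
#' @return A `toy_potential`.
#' @examples
#' pot <- double_well(barrier = 1.6)
#' pot$fun(c(-0.17, 6.0)) # 0 and delta
#' @export
double_well <- function(well_a = -0.17, well_b = 6.0, barrier = 1.6,
                        delta = 0.5, wall_k = 2, wall_extent = 2) {
  if (well_b <= well_a) abort("`well_b` must exceed `well_a`.")
  if (barrier < 0 || delta < 0) abort("`barrier` and `delta` must be >= 0.")
  xm <- (well_a + well_b) / 2
  top <- delta + barrier
  fun <- function(x) {
    ifelse(
      x < well_a, wall_k * (x - well_a)^2,
      ifelse(
        x <= xm, top / 2 * (1 - cos(pi * (x - well_a) / (xm - well_a))),
        ifelse(
          x <= well_b,
          delta + (top - delta) / 2 * (1 + cos(pi * (x - xm) / (well_b - xm))),
          delta + wall_k * (x - well_b)^2
        )
      )
    )
  }
  pot <- toy_potential(fun = fun,
                       domain = c(well_a - wall_extent, well_b + wall_extent))
  pot$wells <- c(a = well_a, b = well_b)
  pot$barrier <- barrier
  pot$delta <- delta
  pot
}

#' Boltzmann samples of R_c from a toy potential
#'
#' Draws i.i.d. samples from the density proportional to `exp(-W/RT)` by
#' inverse-CDF lookup on a fine grid over the potential's domain.
#' Bit-reproducible given the seed.
#'
#' @param potential A [toy_potential()].
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param thermo A [thermo()] object.
#' @param grid_res Inverse-CDF grid resolution (Angstrom, default 1e-3).
#' @return Numeric vector of samples with attributes `seed` and `n`.
#' @export
sample_rc <- function(potential, n, seed, thermo = loopstate::thermo(),
                      grid_res = 1e-3) {
  if (n < 1) abort("`n` must be >= 1.")
  g <- seq(potential$domain[1], potential$domain[2], by = grid_res)
  Wg <- potential$fun(g)
  if (any(!is.finite(Wg))) abort("Potential is non-finite on its domain.")
  dens <- exp(-(Wg - min(Wg)) / thermo$RT)
  cdf <- cumsum((head(dens, -1) + tail(dens, -1)) / 2) * grid_res
  cdf <- c(0, cdf) / max(cumsum((head(dens, -1) + tail(dens, -1)) / 2) * grid_res)
  keep <- c(TRUE, diff(cdf) > 0)
  out <- local_seed(seed, {
    u <- runif(n)
    approx(cdf[keep], g[keep], xout = u, rule = 2)$y
  })
  structure(out, seed = seed, n = n)
}

#' Toy anchor layout for 3-D embedding
#'
#' A minimal geometry emulator for the loop coordinate: the P1 and P2
#' anchor Calphas sit at fixed positions `separation` apart, and the loop
#' points (the E17/N18 Calphas defining the turn point j, plus one
#' side-chain pseudo-atom per tracked residue) ride on a straight path
#' offset from the P1-P2 axis. The induced map t -> R_c is precomputed on
#' a grid, checked to be strictly monotone, and inverted by interpolation
#' in [embed_frames()].
#'
#' @param separation P1-P2 distance (Angstrom, default 15).
#' @param path_offset Perpendicular offset of the loop path from the
#'   P1-P2 axis (Angstrom).
#' @param n_grid Resolution of the precomputed t -> R_c map.
#' @return A list of class `toy_anchor_layout`: `atoms` (template),
#'   `moving` (indices of path atoms), `path(t)` (coordinates of the moving
#'   atoms), `rc_map` (tibble `t`, `Rc`), `rc_range`.
#' @export
toy_anchor_layout <- function(separation = 15, path_offset = 2,
                              n_grid = 2001) {
  half <- separation / 2
  # static anchor Calphas: centroids exactly at (-half,0,0) and (half,0,0)
  sq <- rbind(c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  p1_xyz <- sweep(sq, 2, c(-half, 0, 0), `+`)
  p2_xyz <- sweep(sq, 2, c(half, 0, 0), `+`)
  static <- tibble(
    name = "CA",
    resname = c("ARG", "HIS", "GLY", "ARG", "LEU", "ALA", "TRP", "PHE"),
    resno = c(44L, 45L, 97L, 98L, 28L, 29L, 30L, 31L),
    chain = "A", element = "C", insert = "", alt = "",
    x = c(p1_xyz[, 1], p2_xyz[, 1]),
    y = c(p1_xyz[, 2], p2_xyz[, 2]),
    z = c(p1_xyz[, 3], p2_xyz[, 3])
  )
  moving_tpl <- tibble(
    name = c("CA", "CA", "CD", "CG", "SD", "CG"),
    resname = c("GLU", "ASN", "GLU", "ASN", "MET", "PRO"),
    resno = c(17L, 18L, 17L, 18L, 20L, 21L),
    chain = "A",
    element = c("C", "C", "C", "C", "S", "C"),
    insert = "", alt = "", x = 0, y = 0, z = 0
  )
  # fixed offsets of the moving atoms around the path point; the two turn
  # Calphas are placed symmetrically so j equals the path point exactly
  offs <- rbind(
    c(0, 0.4, 0.3), c(0, -0.4, -0.3),
    c(0.3, 0.5, 0), c(-0.3, 0.5, 0), c(0.3, -0.5, 0), c(-0.3, -0.5, 0)
  )
  x_start <- half - 4.5 # toward P2: occluded-like, low R_c
  x_end <- -half + 2.5  # toward P1: closed-like, high R_c
  path <- function(t) {
    px <- x_start + t * (x_end - x_start)
    lapply(seq_along(t), function(i) {
      sweep(offs, 2, c(px[i], path_offset, 0), `+`)
    })
  }
  atoms <- bind_rows(static, moving_tpl)
  layout <- structure(
    list(atoms = atoms, moving = nrow(static) + seq_len(nrow(moving_tpl)),
         path = path, rc_map = NULL, rc_range = NULL),
    class = "toy_anchor_layout"
  )
  tg <- seq(0, 1, length.out = n_grid)
  fr <- layout_frames(layout, tg)
  rc <- suppressWarnings(descriptors_from_frames(fr))$Rc
  if (any(diff(rc) <= 0)) abort("Layout map t -> R_c is not strictly monotone.")
  layout$rc_map <- tibble(t = tg, Rc = rc)
  layout$rc_range <- range(rc)
  layout
}

# Frames realizing path parameters t (vector) in a layout.
layout_frames <- function(layout, t) {
  n_at <- nrow(layout$atoms)
  xyz <- matrix(rep(as.vector(t(as.matrix(layout$atoms[, c("x", "y", "z")]))),
                    each = length(t)),
                nrow = length(t))
  mv <- layout$path(t)
  for (k in seq_along(layout$moving)) {
    a <- layout$moving[k]
    m <- t(vapply(mv, function(mm) mm[k, ], numeric(3)))
    xyz[, 3 * a - 2] <- m[, 1]
    xyz[, 3 * a - 1] <- m[, 2]
    xyz[, 3 * a] <- m[, 3]
  }
  loop_frames(layout$atoms, xyz)
}

#' Embed R_c samples as 3-D trajectory frames
#'
#' Inverts the layout's monotone t -> R_c map by interpolation and emits
#' one frame per sample whose atoms realize the anchor geometry. Round
#' trip: [rc_timeseries()] on the result recovers the input samples to
#' within 0.01 Angstrom.
#'
#' @param rc_samples Numeric vector of target R_c values.
#' @param layout A [toy_anchor_layout()].
#' @return A [loop_frames()] object.
#' @export
embed_frames <- function(rc_samples, layout = toy_anchor_layout()) {
  rc_samples <- as.numeric(rc_samples)
  if (length(rc_samples) == 0) {
    return(loop_frames(layout$atoms,
                       matrix(numeric(0), nrow = 0,
                              ncol = 3 * nrow(layout$atoms))))
  }
  out_of_range <- which(rc_samples < layout$rc_range[1] - 1e-9 |
                          rc_samples > layout$rc_range[2] + 1e-9)
  if (length(out_of_range)) {
    abort(paste0("Sample(s) outside the layout's achievable R_c range [",
                 signif(layout$rc_range[1], 4), ", ",
                 signif(layout$rc_range[2], 4), "]: index ",
                 paste(head(out_of_range, 5), collapse = ", ")))
  }
  t <- approx(layout$rc_map$Rc, layout$rc_map$t, xout = rc_samples,
              rule = 2)$y
  layout_frames(layout, t)
}

#' Umbrella-biased samples by Metropolis Monte Carlo
#'
#' For each window, samples the biased potential `W(x) + 1/2 k (x - x0)^2`
#' with a Metropolis random walk. The step size is adapted during burn-in
#' toward a 30-50% acceptance rate; the burn-in (first 10% of the chain)
#' is discarded. Deterministic given the seed.
#'
#' @param potential A [toy_potential()].
#' @param centers Window centers (Angstrom).
#' @param k Force constant, kcal/(mol*A^2) (default 10; may be a vector,
#'   0 for unbiased windows).
#' @param n_per_window Retained samples per window.
#' @param seed Integer seed (window w uses `seed + w`).
#' @param thermo A [thermo()] object.
#' @param thin Keep every `thin`-th Metropolis step (default 5).
#' @param step Initial proposal half-width; default adapted from k.
#' @return A list of [umbrella_window()] objects with a `provenance`
#'   attribute (seed, n, acceptance rates).
#' @export
gen_umbrella_samples <- function(potential, centers, k = 10, n_per_window,
                                 seed, thermo = loopstate::thermo(),
                                 thin = 5, step = NULL) {
  k <- rep_len(k, length(centers))
  acc_rates <- numeric(length(centers))
  windows <- vector("list", length(centers))
  for (w in seq_along(centers)) {
    win <- umbrella_window(numeric(0), center = centers[w], k = k[w])
    u_fun <- function(x) potential$fun(x) + bias_energy(x, win)
    st <- if (is.null(step)) {
      if (k[w] > 0) 2 * sqrt(thermo$RT / k[w]) else diff(potential$domain) / 8
    } else {
      step
    }
    n_keep <- n_per_window
    n_steps <- ceiling(n_keep * thin / 0.9)
    burn <- n_steps - n_keep * thin
    res <- local_seed(seed + w, {
      x <- if (k[w] > 0) centers[w] else mean(potential$domain)
      ux <- u_fun(x)
      kept <- numeric(n_keep)
      ik <- 0L
      acc_burn <- 0L
      n_acc <- 0L
      n_post <- 0L
      prop <- runif(n_steps, -1, 1)
      uacc <- runif(n_steps)
      for (s in seq_len(n_steps)) {
        xn <- x + st * prop[s]
        accepted <- FALSE
        if (xn >= potential$domain[1] && xn <= potential$domain[2]) {
          un <- u_fun(xn)
          if (uacc[s] < exp(-(un - ux) / thermo$RT)) {
            x <- xn; ux <- un
            accepted <- TRUE
          }
        }
        if (s <= burn) {
          # adapt the step toward a 30-50% acceptance rate during burn-in
          acc_burn <- acc_burn + accepted
          if (s %% 50 == 0) {
            r <- acc_burn / 50
            acc_burn <- 0L
            if (r < 0.3) st <- st * 0.8 else if (r > 0.5) st <- st * 1.25
          }
        } else {
          n_post <- n_post + 1L
          n_acc <- n_acc + accepted
          if ((s - burn) %% thin == 0) {
            ik <- ik + 1L
            kept[ik] <- x
          }
        }
      }
      list(kept = kept[seq_len(ik)], acc = n_acc / max(1L, n_post))
    })
    if (res$acc == 0) {
      abort(paste0("Zero Metropolis acceptance after burn-in in window ", w, "."))
    }
    acc_rates[w] <- res$acc
    windows[[w]] <- umbrella_window(res$kept, center = centers[w], k = k[w])
  }
  structure(windows,
            provenance = list(seed = seed, n_per_window = n_per_window,
                              acceptance = acc_rates))
}

#' Ideal ionic/solvent configurations in a periodic box
#'
#' Uniform-density (ideal-gas) particle frames: per frame and species, a
#' Poisson-distributed count at the stated density, placed uniformly in
#' the cubic box, optionally with a hard-core exclusion diameter. These
#' frames exactly realize the uniform-fluid assumptions of the RDF and
#' potential oracles.
#'
#' @param box_edge Cubic box edge (Angstrom).
#' @param species Tibble `label`, `q`, `density` (particles/A^3).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param exclusion Hard-core minimum distance between particles
#'   (Angstrom, default 0 = ideal gas).
#' @param max_attempts Placement attempts per particle under exclusion.
#' @return Particle tibble (`frame`, `label`, `q`, `x`, `y`, `z`) with
#'   attributes `box_edge`, `species`, `seed`.
#' @export
gen_ionic_config <- function(box_edge, species, n_frames, seed,
                             exclusion = 0, max_attempts = 10000) {
  stopifnot(all(c("label", "q", "density") %in% names(species)))
  if (any(species$density < 0)) abort("Densities must be >= 0.")
  V <- box_edge^3
  out <- local_seed(seed, {
    res <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      counts <- rpois(nrow(species), species$density * V)
      n_tot <- sum(counts)
      lab <- rep(species$label, counts)
      qq <- rep(species$q, counts)
      if (exclusion <= 0) {
        pos <- matrix(runif(3 * n_tot, 0, box_edge), ncol = 3)
      } else {
        pos <- matrix(NA_real_, nrow = n_tot, ncol = 3)
        for (i in seq_len(n_tot)) {
          done <- FALSE
          for (att in seq_len(max_attempts)) {
            p <- runif(3, 0, box_edge)
            if (i == 1 ||
                min(min_image_dist(p, pos[seq_len(i - 1), , drop = FALSE],
                                   box_edge)) >= exclusion) {
              pos[i, ] <- p
              done <- TRUE
              break
            }
          }
          if (!done) {
            abort(paste0("Exclusion packing infeasible: particle ", i,
                         " in frame ", f, "."))
          }
        }
      }
      res[[f]] <- tibble(frame = f, label = lab, q = qq,
                         x = pos[, 1], y = pos[, 2], z = pos[, 3])
    }
    bind_rows(res)
  })
  structure(out, box_edge = box_edge, species = species, seed = seed)
}

#' Toy structure for a target conformer class
#'
#' Builds a minimal, PDB-writable structure whose computed R_c lands at
#' the midpoint of the target class's R_c band (bands clipped to the
#' layout's achievable range).
#'
#' @param target_class One of "occluded", "intermediate", "open", "closed".
#' @param layout A [toy_anchor_layout()].
#' @param boundaries See [class_boundaries()].
#' @return An atom table (see [read_structure()]) with a `type` column.
#' @export
gen_toy_structure <- function(target_class = c("occluded", "intermediate",
                                               "open", "closed"),
                              layout = toy_anchor_layout(),
                              boundaries = class_boundaries()) {
  target_class <- match.arg(target_class)
  b <- boundaries
  lo <- layout$rc_range[1]
  hi <- layout$rc_range[2]
  band <- switch(target_class,
    occluded = c(lo, b[["occluded"]]),
    intermediate = c(b[["occluded"]], b[["intermediate"]]),
    open = c(b[["intermediate"]], b[["closed"]]),
    closed = c(b[["closed"]], hi)
  )
  band <- c(max(band[1], lo), min(band[2], hi))
  if (band[1] >= band[2]) {
    abort(paste0("Class '", target_class, "' is not achievable in this layout."))
  }
  target <- mean(band)
  fr <- embed_frames(target, layout)
  atoms <- frame_atoms(fr, 1)
  atoms$type <- "ATOM"
  atoms
}
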