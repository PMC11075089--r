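test_that("RDF of an ideal gas is unity and matches brute-force counts", {
  box <- 40
  spc <- tibble::tibble(label = "K+", q = 1, density = 0.008)
  pf <- gen_ionic_config(box, spc, n_frames = 200, seed = 21)
  ref <- reference_point(position = c(20, 20, 20))
  g <- rdf(pf, ref, box, dr = 0.25, r_max = 19)
  sel <- g$r >= 5
  # 3-sigma Monte-Carlo bound on the mean deviation from unity
  shell_counts <- g$count[sel] * 200
  sigma_bar <- mean(sqrt(shell_counts) / shell_counts)
  expect_lt(mean(abs(g$g[sel] - 1)), 3 * sigma_bar)

  # no particles of a species: g identically zero
  g0 <- rdf(pf[0, ], ref, box, dr = 0.5, r_max = 10,
            densities = tibble::tibble(label = "K+", density = 0.008))
  expect_equal(nrow(g0), 0)

  # hand-placed particles: shell counts equal a brute-force tally
  p <- tibble::tibble(frame = 1, label = "X",  q = 1,
                      x = c(21, 24, 28, 20), y = 20, z = c(20, 20, 20, 26))
  gh <- rdf(p, ref, box, dr = 2, r_max = 10)
  expect_equal(gh$count, c(1, 0, 1, 1, 1)) # r = 1, 4, 6, 8
  expect_error(rdf(p, ref, box, dr = 1, r_max = 30), "half the box")
})

test_that("particle summation reproduces the Coulomb closed form", {
  ref <- reference_point(position = c(0, 0, 0))
  p <- tibble::tibble(frame = 1, label = "Na+", q = 1, x = 5, y = 0, z = 0)
  prof <- phi_particle_sum(p, ref, box_edge = 40, dR = 1, R_max = 10)
  expect_equal(prof$phi[prof$R < 5], rep(0, 4))
  expect_equal(prof$phi[prof$R >= 5], rep(332.0637 / 5, 6))

  # no particles at all
  empty <- phi_particle_sum(p[0, ], ref, 40, dR = 1, R_max = 10)
  expect_equal(empty$phi, rep(0, 10))

  # degenerate particle at the reference point
  origin <- tibble::tibble(frame = 1, label = "X", q = 1, x = 0, y = 0, z = 0)
  expect_error(phi_particle_sum(origin, ref, 40), "exactly at the reference")
  near <- tibble::tibble(frame = 1:2, label = "X", q = 1,
                         x = c(0.1, 5), y = 0, z = 0)
  expect_warning(pr <- phi_particle_sum(near, ref, 40, dR = 1, R_max = 10),
                 "rejected")
  expect_equal(pr$phi[10], 332.0637 / 5) # only the clean frame remains
})

test_that("potential superposes exactly over particle sets", {
  box <- 30
  ref <- reference_point(position = c(15, 15, 15))
  set.seed(31)
  mk <- function(n, q) tibble::tibble(
    frame = rep(1:5, each = n), label = "X", q = q,
    x = runif(5 * n, 0, box), y = runif(5 * n, 0, box), z = runif(5 * n, 0, box)
  )
  a <- mk(40, 1); b <- mk(25, -2)
  pa <- phi_particle_sum(a, ref, box, dR = 0.5, R_max = 14, reject_within = 0)
  pb <- phi_particle_sum(b, ref, box, dR = 0.5, R_max = 14, reject_within = 0)
  pab <- phi_particle_sum(dplyr::bind_rows(a, b), ref, box, dR = 0.5,
                          R_max = 14, reject_within = 0)
  expect_equal(pab$phi, pa$phi + pb$phi, tolerance = 1e-12)
})

test_that("for positive charges the cumulative potential is non-decreasing", {
  box <- 40
  spc <- tibble::tibble(label = "K+", q = 1, density = 0.005)
  pf <- gen_ionic_config(box, spc, n_frames = 30, seed = 41)
  ref <- reference_point(position = c(20, 20, 20))
  prof <- phi_particle_sum(pf, ref, box, dR = 0.2, R_max = 19,
                           reject_within = 0)
  expect_true(all(diff(prof$phi) >= -1e-9))
})

test_that("RDF-integral and particle-summation routes agree", {
  box <- 40
  spc <- tibble::tibble(label = "K+", q = 1, density = 0.01)
  pf <- gen_ionic_config(box, spc, n_frames = 160, seed = 51) # ~1e5 samples
  ref <- reference_point(position = c(20, 20, 20))
  g <- rdf(pf, ref, box, dr = 0.05, r_max = 19)
  p1 <- phi_particle_sum(pf, ref, box, dR = 0.05, R_max = 19,
                         reject_within = 0)
  p2 <- phi_from_rdf(g, charges = spc[, c("label", "q")])
  expect_equal(nrow(p1), nrow(p2))
  expect_lt(max(abs(p1$R - p2$R)), 1e-9)
  # the innermost shells hold O(1) ions, so both estimators there are
  # dominated by within-shell positioning noise; compare from R = 2 A out
  sel <- p1$R >= 2
  rel <- abs(p1$phi - p2$phi)[sel] / pmax(abs(p1$phi[sel]), 1e-12)
  expect_true(all(rel <= 0.02 | abs(p1$phi - p2$phi)[sel] <= 0.5))

  # analytic check: g == 1 at exactly the nominal density gives the
  # 2 pi rho q kC R^2 closed form
  gg <- g
  gg$g <- 1
  attr(gg, "densities") <- tibble::tibble(label = "K+", density = 0.01)
  p3 <- phi_from_rdf(gg, charges = spc[, c("label", "q")])
  expect_equal(p3$phi, 2 * pi * 0.01 * 1 * 332.0637 * p3$R^2,
               tolerance = 1e-10)
  # zero density: zero potential
  attr(gg, "densities") <- tibble::tibble(label = "K+", density = 0)
  expect_equal(max(abs(phi_from_rdf(gg, spc[, c("label", "q")])$phi)), 0)
})

test_that("a neutral 2:1 salt has zero mean potential within noise", {
  box <- 40
  spc <- tibble::tibble(label = c("Ca2+", "Cl-"), q = c(2, -1),
                        density = c(0.002, 0.004))
  pf <- gen_ionic_config(box, spc, n_frames = 400, seed = 61)
  ref <- reference_point(position = c(20, 20, 20))
  prof <- suppressWarnings(
    phi_particle_sum(pf, ref, box, dR = 1, R_max = 19, reject_within = 0.5)
  )
  sel <- prof$R >= 3
  expect_true(all(abs(prof$phi[sel]) <= 3 * prof$err[sel]))
})

test_that("solvent potentials use TIP3P charges", {
  ref <- reference_point(position = c(0, 0, 0))
  w <- tibble::tibble(frame = 1, label = c("O", "H1", "H2"),
                      x = c(4, 4.6, 4.2), y = c(0, 0.4, -0.7), z = 0)
  prof <- phi_solvent(w, ref, box_edge = 40, dR = 0.5, R_max = 10)
  rO <- 4; rH1 <- sqrt(4.6^2 + 0.16); rH2 <- sqrt(4.2^2 + 0.49)
  expected <- 332.0637 * (-0.834 / rO + 0.417 / rH1 + 0.417 / rH2)
  expect_equal(prof$phi[nrow(prof)], expected, tolerance = 1e-12)

  # a water far beyond R_max contributes nothing
  far <- tibble::tibble(frame = 1, label = c("O", "H1", "H2"),
                        x = 30, y = c(0, 0.5, -0.5), z = 0)
  expect_equal(max(abs(phi_solvent(far, ref, 80, dR = 1, R_max = 10)$phi)), 0)

  # randomly oriented distant waters: dipolar decay toward zero
  set.seed(71)
  n <- 400
  centers <- matrix(runif(3 * n, -35, 35), ncol = 3)
  keep <- sqrt(rowSums(centers^2)) > 12
  centers <- centers[keep, ]
  frames <- lapply(seq_len(nrow(centers)), function(i) {
    u <- rnorm(3); u <- 0.4 * u / sqrt(sum(u^2))
    v <- rnorm(3); v <- 0.4 * v / sqrt(sum(v^2))
    tibble::tibble(frame = 1, label = c("O", "H1", "H2"),
                   x = centers[i, 1] + c(0, u[1], v[1]),
                   y = centers[i, 2] + c(0, u[2], v[2]),
                   z = centers[i, 3] + c(0, u[3], v[3]))
  })
  allw <- dplyr::bind_rows(frames)
  prof <- phi_solvent(allw, ref, box_edge = 200, dR = 5, R_max = 50)
  expect_lt(abs(prof$phi[nrow(prof)]), 5)
})

test_that("the linear free-energy estimate is half q times phi", {
  expect_equal(lfer_free_energy(-1, 10), -5)
  expect_equal(lfer_free_energy(-1, 0), 0)
  expect_equal(lfer_free_energy(-1, 20), 2 * lfer_free_energy(-1, 10))
  expect_equal(lfer_free_energy(2, 3.5), 3.5)
})

test_that("the loop reference point averages the three turn Calphas", {
  atoms <- toy_hand_structure()
  # E17 CA (4,3,1), N18 CA (4,3,-1); add an M20 CA at (5,4,0)
  m20 <- tibble::tibble(name = "CA", resname = "MET", resno = 20L,
                        chain = "A", element = "C", insert = "", alt = "",
                        x = 5, y = 4, z = 0)
  ref <- reference_point(dplyr::bind_rows(atoms, m20))
  expect_equal(ref$position, c(13 / 3, 10 / 3, 0))
  expect_equal(ref$charge, -1)
})
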