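test_that("Boltzmann sampler is seed-deterministic and carries provenance", {
  pot <- double_well()
  a <- sample_rc(pot, 1000, seed = 7)
  b <- sample_rc(pot, 1000, seed = 7)
  expect_identical(a, b)
  expect_equal(attr(a, "seed"), 7)
  expect_equal(attr(a, "n"), 1000)
  c0 <- sample_rc(pot, 1000, seed = 8)
  expect_false(identical(as.numeric(a), as.numeric(c0)))
  bad <- toy_potential(fun = function(x) ifelse(x > 0, Inf, 0),
                       domain = c(-1, 1))
  expect_error(sample_rc(bad, 10, seed = 1), "non-finite")
})

test_that("a flat potential yields uniform samples", {
  flat <- toy_potential(fun = function(x) rep(0, length(x)), domain = c(0, 1))
  s <- sample_rc(flat, 1e5, seed = 12)
  ks <- suppressWarnings(stats::ks.test(as.numeric(s), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a deep single well confines all samples", {
  pot <- toy_potential(fun = function(x) 50 * (x - 3)^2, domain = c(0, 6))
  s <- sample_rc(pot, 1e4, seed = 13)
  # >= 20 RT beyond ~0.35 A from the minimum
  expect_true(all(abs(s - 3) < 0.5))
  # Gaussian limit: sd = sqrt(RT / (2 * 50))
  expect_equal(sd(s), sqrt(thermo()$RT / 100), tolerance = 0.05)
})

test_that("embedding inverts the layout map within 0.01 A", {
  lay <- toy_anchor_layout()
  expect_true(all(diff(lay$rc_map$Rc) > 0)) # strictly monotone map
  targets <- seq(lay$rc_range[1] + 0.1, lay$rc_range[2] - 0.1,
                 length.out = 500)
  fr <- embed_frames(targets, lay)
  rc <- rc_timeseries(fr)$Rc
  expect_lt(max(abs(rc - targets)), 0.01)

  expect_equal(n_frames(embed_frames(numeric(0), lay)), 0)
  expect_error(embed_frames(c(1, 99), lay), "achievable")
})

test_that("umbrella sampler matches the direct sampler when unbiased", {
  pot <- double_well(barrier = 1)
  wins <- gen_umbrella_samples(pot, centers = NA, k = 0,
                               n_per_window = 4000, seed = 14)
  direct <- sample_rc(pot, 4000, seed = 15)
  ks <- suppressWarnings(
    stats::ks.test(wins[[1]]$samples, as.numeric(direct))
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("a stiff umbrella window approaches its Gaussian limit", {
  pot <- toy_potential(fun = function(x) rep(0, length(x)), domain = c(0, 10))
  wins <- gen_umbrella_samples(pot, centers = 5, k = 1000,
                               n_per_window = 4000, seed = 16)
  s <- wins[[1]]$samples
  expect_equal(mean(s), 5, tolerance = 0.01)
  expect_equal(sd(s), sqrt(thermo()$RT / 1000), tolerance = 0.1)
  # reproducibility
  wins2 <- gen_umbrella_samples(pot, centers = 5, k = 1000,
                                n_per_window = 4000, seed = 16)
  expect_identical(wins[[1]]$samples, wins2[[1]]$samples)
  prov <- attr(wins, "provenance")
  expect_true(all(prov$acceptance > 0.2 & prov$acceptance < 0.65))
})

test_that("ideal ionic configurations have Poisson statistics", {
  box <- 30
  spc <- tibble::tibble(label = c("Ca2+", "Cl-"), q = c(2, -1),
                        density = c(0.001, 0.002))
  pf <- gen_ionic_config(box, spc, n_frames = 1000, seed = 17)
  V <- box^3
  for (l in spc$label) {
    lam <- spc$density[spc$label == l] * V
    counts <- tabulate(pf$frame[pf$label == l], nbins = 1000)
    expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 1000))
  }
  # global neutrality in expectation
  expect_lt(abs(sum(pf$q)) / 1000, 3 * sqrt(2^2 * 0.001 * V + 0.002 * V) /
              sqrt(1000))
  # determinism and provenance
  pf2 <- gen_ionic_config(box, spc, n_frames = 1000, seed = 17)
  expect_identical(pf, pf2)
  expect_equal(attr(pf, "seed"), 17)
  # zero density gives empty frames
  none <- gen_ionic_config(box, dplyr::mutate(spc, density = 0), 5, seed = 1)
  expect_equal(nrow(none), 0)
  # infeasible exclusion packing errors out
  dense <- tibble::tibble(label = "X", q = 1, density = 0.05)
  expect_error(gen_ionic_config(10, dense, 1, seed = 2, exclusion = 8,
                                max_attempts = 50), "infeasible")
})

test_that("hard-core exclusion is honoured", {
  spc <- tibble::tibble(label = "X", q = 1, density = 0.002)
  pf <- gen_ionic_config(20, spc, n_frames = 20, seed = 18, exclusion = 3)
  for (f in unique(pf$frame)) {
    xyz <- as.matrix(pf[pf$frame == f, c("x", "y", "z")])
    if (nrow(xyz) < 2) next
    dmin <- min(stats::dist(xyz)) # box 20, exclusion 3: interior distances
    for (i in seq_len(nrow(xyz) - 1)) {
      dd <- sweep(xyz[(i + 1):nrow(xyz), , drop = FALSE], 2, xyz[i, ])
      dd <- dd - 20 * round(dd / 20)
      expect_gte(min(sqrt(rowSums(dd^2))), 3)
    }
  }
})

test_that("toy structures land in their target class and survive PDB I/O", {
  lay <- toy_anchor_layout()
  for (cls in c("occluded", "intermediate", "open", "closed")) {
    atoms <- gen_toy_structure(cls, lay)
    desc <- compute_rc(atoms)
    expect_equal(desc$class, cls)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_structure(atoms, f)
    back <- read_structure(f)
    expect_equal(compute_rc(back)$Rc, desc$Rc, tolerance = 1e-3)
  }
})

test_that("the full synthetic pipeline recovers generator barriers", {
  # scaled-down smoke version of the end-to-end recovery (the acceptance
  # suite runs it at full size): samples -> frames -> R_c -> PMF -> barrier
  pot <- double_well(barrier = 1.6)
  lay <- toy_anchor_layout()
  s <- sample_rc(pot, 2e5, seed = 19)
  fr <- embed_frames(s, lay)
  prof <- pool_pmf(list(rc_timeseries(fr)), bin_width = 0.2,
                   range = pot$domain)
  bh <- barrier_height(prof, well_a = c(-1.5, 1.5), well_b = c(4.5, 7.5))
  expect_equal(bh$barrier, 1.6, tolerance = 0.15 / 1.6)
})
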