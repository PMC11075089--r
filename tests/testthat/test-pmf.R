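test_that("histograms normalize to unit probability", {
  h <- histogram_rc(rep(1.0, 100), bin_width = 0.2, range = c(0, 2))
  expect_equal(sum(h$density * 0.2), 1)
  expect_equal(max(h$density), 5.0) # single nonempty bin
  expect_equal(sum(h$count), 100)

  set.seed(1)
  u <- runif(20000)
  h <- histogram_rc(u, bin_width = 0.1, range = c(0, 1))
  expect_lt(max(abs(h$density - 1)), 5 * sqrt(0.1 / (20000 * 0.1^2)))

  expect_error(histogram_rc(numeric(0)), "at least one")
  expect_error(histogram_rc(1, bin_width = 0), "bin_width")
})

test_that("Boltzmann inversion gives -RT ln density with min at zero", {
  # flat density -> W identically zero
  h <- histogram_rc(rep(seq(0.1, 1.9, by = 0.2), each = 10),
                    bin_width = 0.2, range = c(0, 2))
  p <- pmf_from_density(h)
  expect_equal(p$W, rep(0, 10))

  # density ratio 2 at 298.16 K -> RT ln 2 = 0.4107 kcal/mol
  h2 <- histogram_rc(c(rep(0.1, 200), rep(0.3, 100)), 0.2, c(0, 0.4))
  p2 <- pmf_from_density(h2)
  expect_equal(p2$W[2] - p2$W[1], 0.4107, tolerance = 1e-4 / 0.4107)

  # single sampled bin: zero there, masked elsewhere
  h3 <- histogram_rc(rep(5, 10), 0.2, c(0, 9))
  p3 <- pmf_from_density(h3)
  expect_equal(sum(is.finite(p3$W)), 1)
  expect_equal(min(p3$W, na.rm = TRUE), 0)
})

test_that("pooling sums counts before normalization", {
  set.seed(2)
  a <- rnorm(500, 2, 0.5); b <- rnorm(300, 5, 0.3); c0 <- rnorm(200, 2, 1)
  pooled <- pool_pmf(list(a, b, c0))
  concat <- pmf_from_samples(c(a, b, c0))
  expect_equal(pooled, concat)
  # three copies of one set give the same profile as one copy
  expect_equal(pool_pmf(list(a, a, a))$W, pmf_from_samples(a)$W)
  # disjoint supports both covered
  two <- pool_pmf(list(rep(1, 10), rep(6, 10)))
  expect_equal(sum(two$n > 0), 2)
  expect_error(pool_pmf(list()), "non-empty")
})

test_that("harmonic bias follows the half-k convention", {
  w <- umbrella_window(numeric(0), center = 5, k = 10)
  expect_equal(bias_energy(5, w), 0)
  expect_equal(bias_energy(5.2, w), 0.2) # 1/2 * 10 * 0.04
  expect_equal(bias_energy(5.2, w, convention = "full"), 0.4)
  w0 <- umbrella_window(numeric(0), k = 0)
  expect_equal(bias_energy(c(-10, 0, 10), w0), c(0, 0, 0))
})

test_that("WHAM reduces to Boltzmann inversion without bias", {
  set.seed(3)
  s <- rnorm(4000, 3, 1)
  w <- wham_join(list(umbrella_window(s)), bin_width = 0.2, range = c(-4, 9))
  p <- pmf_from_samples(s, bin_width = 0.2, range = c(-4, 9))
  expect_equal(w$W, p$W, tolerance = 1e-9)
  expect_equal(w$Rc, p$Rc)

  # two identical unbiased windows give the same profile as either alone
  w2 <- wham_join(list(umbrella_window(s), umbrella_window(s)),
                  bin_width = 0.2, range = c(-4, 9))
  expect_equal(w2$W, w$W, tolerance = 1e-9)

  # all-unbiased WHAM equals pooling exactly on the same binning
  s2 <- rnorm(3000, 5, 0.8)
  wj <- wham_join(list(umbrella_window(s), umbrella_window(s2)),
                  bin_width = 0.2, range = c(-4, 9))
  pp <- pool_pmf(list(s, s2), bin_width = 0.2, range = c(-4, 9))
  expect_equal(wj$W, pp$W, tolerance = 1e-9)
})

test_that("WHAM is invariant to window ordering and detects gaps", {
  pot <- double_well(barrier = 2)
  wins <- gen_umbrella_samples(pot, centers = seq(-1, 7, by = 0.4), k = 10,
                               n_per_window = 400, seed = 8)
  fwd <- wham_join(wins, bin_width = 0.2, range = pot$domain)
  rev <- wham_join(rev(wins), bin_width = 0.2, range = pot$domain)
  expect_equal(fwd$W, rev$W, tolerance = 1e-6)

  gap <- list(umbrella_window(rnorm(200, 0, 0.1), center = 0, k = 10),
              umbrella_window(rnorm(200, 8, 0.1), center = 8, k = 10))
  expect_error(wham_join(gap, bin_width = 0.2), "overlap")
})

test_that("profiles ignore constant shifts of the input potential", {
  # sampling from W and W + const yields the same profile in distribution;
  # with identical seeds the samples are identical
  pot1 <- toy_potential(fun = function(x) x^2, domain = c(-2, 2))
  pot2 <- toy_potential(fun = function(x) x^2 + 7, domain = c(-2, 2))
  s1 <- sample_rc(pot1, 1000, seed = 5)
  s2 <- sample_rc(pot2, 1000, seed = 5)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)
})

test_that("block errors recover the two-block closed form", {
  # blocks of equal size; one bin's density differs by a factor of 2
  blk1 <- c(rep(0.1, 100), rep(0.5, 100))
  blk2 <- c(rep(0.1, 150), rep(0.5, 50))
  be <- block_errors(c(blk1, blk2), n_blocks = 2, bin_width = 0.2,
                     range = c(0, 0.6))
  RT <- thermo()$RT
  expect_equal(be$err[be$Rc == 0.5], RT * log(2) / 2, tolerance = 1e-9)
  # identical blocks have zero error
  be0 <- block_errors(c(blk1, blk1), n_blocks = 2, bin_width = 0.2,
                      range = c(0, 0.6))
  expect_equal(max(be0$err, na.rm = TRUE), 0)
  expect_error(block_errors(blk1, n_blocks = 1), "n_blocks")
  expect_error(block_errors(c(1, 2), n_blocks = 3), "Fewer samples")
})

test_that("barrier is measured from the shallower well", {
  # flat profile: zero barrier
  h <- histogram_rc(rep(seq(0.1, 6, by = 0.2), each = 5), 0.2, c(0, 6))
  flat <- pmf_from_density(h)
  b <- barrier_height(flat, c(0, 1), c(5, 6))
  expect_equal(b$barrier, 0)
  expect_error(barrier_height(flat, c(0, 3), c(2, 6)), "disjoint")

  # asymmetric double well: barrier = top - shallower minimum
  pot <- double_well(well_a = 0, well_b = 5, barrier = 2, delta = 1)
  s <- sample_rc(pot, 2e5, seed = 9)
  prof <- pmf_from_samples(s, bin_width = 0.2, range = pot$domain)
  bh <- barrier_height(prof, c(-1, 2), c(4, 6))
  expect_equal(bh$barrier, 2, tolerance = 0.1)
  expect_equal(bh$w_b - bh$w_a, 1, tolerance = 0.1)
})

test_that("fep tidiers and plot accessors work", {
  s <- sample_rc(double_well(barrier = 1), 5000, seed = 10)
  prof <- pmf_from_samples(s, n_blocks = 3)
  td <- tidy(prof)
  expect_true(all(c("Rc", "W", "err", "sampled") %in% names(td)))
  gl <- glance(prof)
  expect_equal(gl$n_samples, 5000)
  expect_equal(gl$temperature, 298.16)
  expect_s3_class(autoplot(prof), "ggplot")
})
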