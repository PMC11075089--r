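# Free-energy profiles along R_c: Boltzmann inversion of binned densities,
# pooling across simulations, WHAM joining of (possibly umbrella-biased)
# windows, block error bars, and barrier measurement.

new_fep <- function(tbl, thermo, bin_width, convergence = NULL) {
  structure(as_tibble(tbl),
            thermo = thermo, bin_width = bin_width,
            convergence = convergence,
            class = c("fep", class(tibble())))
}

#' Histogram of R_c samples
#'
#' Uniform-width histogram with a probability density normalized over all
#' samples, so that `sum(density * bin_width) == 1`.
#'
#' @param samples Numeric vector of R_c values (Angstrom), or a data frame
#'   with an `Rc` column (e.g. from [rc_timeseries()]).
#' @param bin_width Bin width in Angstrom (default 0.2, the umbrella
#'   spacing).
#' @param range Length-2 numeric range to bin over; default `c(-4, 9)`,
#'   extended if samples fall outside.
#' @return A tibble of class `rc_histogram` with columns `lo`, `hi`, `mid`,
#'   `count`, `density`.
#' @export
histogram_rc <- function(samples, bin_width = 0.2, range = c(-4, 9)) {
  samples <- samples_vector(samples)
  if (length(samples) == 0) abort("Need at least one sample.")
  if (!is.numeric(bin_width) || bin_width <= 0) abort("`bin_width` must be > 0.")
  lo <- min(range[1], min(samples))
  hi <- max(range[2], max(samples))
  nb <- ceiling((hi - lo) / bin_width - 1e-9)
  edges <- lo + bin_width * (0:nb)
  idx <- pmin(pmax(floor((samples - lo) / bin_width) + 1, 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  out <- tibble(
    lo = edges[-length(edges)], hi = edges[-1],
    mid = (edges[-length(edges)] + edges[-1]) / 2,
    count = counts,
    density = counts / (length(samples) * bin_width)
  )
  structure(out, bin_width = bin_width, n_samples = length(samples),
            class = c("rc_histogram", class(tibble())))
}

samples_vector <- function(samples) {
  if (is.data.frame(samples)) {
    if (!"Rc" %in% names(samples)) abort("Data-frame input needs an `Rc` column.")
    samples <- samples$Rc
  }
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) abort("Samples must be finite.")
  samples
}

#' Free-energy profile by Boltzmann inversion
#'
#' Converts a binned probability density rho<Rc> into the potential of mean
#' force W(Rc) = -RT ln rho<Rc>, shifted so the minimum over sampled bins is
#' zero. Empty bins are masked (W = NA); no pseudo-counts are ever added.
#'
#' @param hist An [histogram_rc()] result.
#' @param thermo A [thermo()] object (298.16 K default).
#' @return A `fep` tibble with columns `Rc` (bin centers), `W` (kcal/mol),
#'   `err` (NA unless filled by [block_errors()]), `n` (bin counts).
#' @examples
#' h <- histogram_rc(c(rep(1.1, 200), rep(1.3, 100)), bin_width = 0.2,
#'                   range = c(1, 1.4))
#' pmf_from_density(h)$W # 0 and RT*ln(2) = 0.4107
#' @export
pmf_from_density <- function(hist, thermo = loopstate::thermo()) {
  if (!inherits(hist, "rc_histogram")) abort("`hist` must come from histogram_rc().")
  if (all(hist$count == 0)) abort("Histogram has no sampled bins.")
  W <- ifelse(hist$density > 0, -thermo$RT * log(hist$density), NA_real_)
  W <- W - min(W, na.rm = TRUE)
  new_fep(tibble(Rc = hist$mid, W = W, err = NA_real_, n = hist$count),
          thermo, attr(hist, "bin_width"))
}

#' Free-energy profile from raw samples
#'
#' Convenience wrapper: histogram, Boltzmann inversion, and (optionally)
#' per-bin block standard errors in one call.
#'
#' @inheritParams histogram_rc
#' @param thermo A [thermo()] object.
#' @param n_blocks If not `NULL`, fill `err` using [block_errors()] with
#'   this many contiguous blocks.
#' @return A `fep` tibble.
#' @export
pmf_from_samples <- function(samples, thermo = loopstate::thermo(),
                             bin_width = 0.2, range = c(-4, 9),
                             n_blocks = NULL) {
  prof <- pmf_from_density(histogram_rc(samples, bin_width, range), thermo)
  if (!is.null(n_blocks)) {
    be <- block_errors(samples, n_blocks = n_blocks, thermo = thermo,
                       bin_width = bin_width, range = range)
    prof$err <- be$err[match(round(prof$Rc, 9), round(be$Rc, 9))]
  }
  prof
}

#' Pooled free-energy profile from several simulations
#'
#' Pools R_c populations from simulations of identical composition by
#' summing bin counts before normalization; the result is exactly the
#' profile of the concatenated samples.
#'
#' @param sample_sets List of sample vectors (or data frames with `Rc`).
#' @inheritParams pmf_from_samples
#' @return A `fep` tibble.
#' @export
pool_pmf <- function(sample_sets, thermo = loopstate::thermo(),
                     bin_width = 0.2, range = c(-4, 9)) {
  if (!is.list(sample_sets) || length(sample_sets) == 0) {
    abort("`sample_sets` must be a non-empty list of sample vectors.")
  }
  all_s <- unlist(lapply(sample_sets, samples_vector))
  if (length(all_s) == 0) abort("Union of sample sets is empty.")
  pmf_from_samples(all_s, thermo, bin_width, range)
}

#' Umbrella window
#'
#' A (possibly biased) sampling window: harmonic bias center `center`,
#' force constant `k` in kcal/(mol*Angstrom^2) (0 for an unbiased segment),
#' and the R_c samples collected under the bias.
#'
#' @param samples Numeric vector of R_c samples.
#' @param center Bias center x0 (Angstrom); ignored when `k = 0`.
#' @param k Harmonic force constant, kcal/(mol*A^2).
#' @return A list of class `umbrella_window`.
#' @export
umbrella_window <- function(samples, center = NA_real_, k = 0) {
  samples <- samples_vector(samples)
  if (k < 0) abort("`k` must be >= 0.")
  if (k > 0 && !is.finite(center)) abort("Biased windows need a finite center.")
  structure(list(center = center, k = k, samples = samples),
            class = "umbrella_window")
}

#' Harmonic umbrella bias energy
#'
#' `U(x) = 1/2 k (x - x0)^2` by default; `convention = "full"` selects
#' `k (x - x0)^2` for cross-checks against conventions that fold the 1/2
#' into k.
#'
#' @param x Position(s), Angstrom.
#' @param window An [umbrella_window()] (its samples are not used).
#' @param convention `"half"` (default) or `"full"`.
#' @return Bias energy in kcal/mol.
#' @examples
#' bias_energy(5.2, umbrella_window(numeric(0), center = 5.0, k = 10)) # 0.2
#' @export
bias_energy <- function(x, window, convention = c("half", "full")) {
  convention <- match.arg(convention)
  if (window$k == 0) return(rep(0, length(x)))
  pre <- if (convention == "half") 0.5 else 1
  pre * window$k * (x - window$center)^2
}

#' Join sampling windows with WHAM
#'
#' Standard self-consistent weighted-histogram estimator over a shared bin
#' grid: iterates the unbiased density and the per-window free-energy
#' constants f_w until `max |delta f_w| < tol`. Unbiased segments enter
#' with `k = 0`; with all k zero the result equals [pool_pmf()] on the same
#' binning. Windows must form a connected chain of overlapping sampled
#' support.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param thermo A [thermo()] object.
#' @param bin_width Bin width (Angstrom).
#' @param range Binning range; default spans the pooled samples.
#' @param tol Convergence tolerance on the window constants (kcal/mol).
#' @param max_iter Iteration cap.
#' @param convention Bias convention, see [bias_energy()].
#' @return A `fep` tibble; `attr(, "convergence")` holds `iterations`,
#'   `residual` and the window constants `f`.
#' @export
wham_join <- function(windows, thermo = loopstate::thermo(), bin_width = 0.2,
                      range = NULL, tol = 1e-7, max_iter = 100000,
                      convention = c("half", "full")) {
  convention <- match.arg(convention)
  if (!length(windows)) abort("Need at least one window.")
  windows <- lapply(windows, function(w) {
    if (inherits(w, "umbrella_window")) w else do.call(umbrella_window, w)
  })
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  if (!length(all_s)) abort("Windows contain no samples.")
  if (is.null(range)) range <- c(min(all_s), max(all_s))
  lo <- min(range[1], min(all_s))
  nb <- ceiling((max(range[2], max(all_s)) - lo) / bin_width - 1e-9)
  mids <- lo + bin_width * (seq_len(nb) - 0.5)

  W <- length(windows)
  n_wb <- matrix(0, nrow = W, ncol = nb)
  for (w in seq_len(W)) {
    idx <- pmin(pmax(floor((windows[[w]]$samples - lo) / bin_width) + 1, 1L), nb)
    n_wb[w, ] <- tabulate(idx, nbins = nb)
  }
  N_w <- rowSums(n_wb)
  check_window_overlap(n_wb)
  # Boltzmann factor of each window's bias at each bin center
  c_wb <- t(vapply(windows, function(w) {
    exp(-bias_energy(mids, w, convention) / thermo$RT)
  }, numeric(nb)))

  n_b <- colSums(n_wb)
  f <- rep(0, W) # -RT log z_w
  for (iter in seq_len(max_iter)) {
    denom <- colSums(N_w * exp(f / thermo$RT) * c_wb)
    rho <- ifelse(denom > 0, n_b / denom, 0)
    z <- as.vector(c_wb %*% (rho * bin_width))
    f_new <- -thermo$RT * log(z)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) break
  }
  if (resid >= tol) {
    abort(paste0("WHAM did not converge in ", max_iter,
                 " iterations (residual ", signif(resid, 3), ")."))
  }
  denom <- colSums(N_w * exp(f / thermo$RT) * c_wb)
  rho <- ifelse(denom > 0, n_b / denom, 0)
  rho <- rho / sum(rho * bin_width)
  Wv <- ifelse(rho > 0, -thermo$RT * log(rho), NA_real_)
  Wv <- Wv - min(Wv, na.rm = TRUE)
  new_fep(tibble(Rc = mids, W = Wv, err = NA_real_, n = n_b),
          thermo, bin_width,
          convergence = list(iterations = iter, residual = resid, f = f))
}

# Windows must form one connected component of shared sampled bins.
check_window_overlap <- function(n_wb) {
  W <- nrow(n_wb)
  if (W == 1) return(invisible(TRUE))
  seen <- rep(FALSE, W)
  seen[1] <- TRUE
  repeat {
    cover <- colSums(n_wb[seen, , drop = FALSE] > 0) > 0
    add <- which(!seen & (n_wb[, cover, drop = FALSE] %*%
                            rep(1, sum(cover))) > 0)
    if (!length(add)) break
    seen[add] <- TRUE
  }
  if (!all(seen)) {
    abort("Windows do not overlap in sampled support; WHAM cannot join them.")
  }
  invisible(TRUE)
}

#' Per-bin block standard errors of the free-energy profile
#'
#' Splits the samples, in time order, into `n_blocks` contiguous blocks,
#' computes each block's Boltzmann-inverted profile, and reports the
#' standard error of W across blocks per bin.
#'
#' @inheritParams pmf_from_samples
#' @param n_blocks Number of contiguous blocks (default 3, one per
#'   independent simulation).
#' @return A tibble `Rc`, `err` (kcal/mol; NA where fewer than 2 blocks
#'   sample a bin).
#' @export
block_errors <- function(samples, n_blocks = 3, thermo = loopstate::thermo(),
                         bin_width = 0.2, range = c(-4, 9)) {
  samples <- samples_vector(samples)
  if (n_blocks < 2) abort("`n_blocks` must be >= 2.")
  if (length(samples) < n_blocks) abort("Fewer samples than blocks.")
  cuts <- floor(seq(0, length(samples), length.out = n_blocks + 1))
  # fixed grid shared by all blocks
  lo <- min(range[1], min(samples))
  hi <- max(range[2], max(samples))
  Wmat <- NULL
  for (b in seq_len(n_blocks)) {
    blk <- samples[(cuts[b] + 1):cuts[b + 1]]
    h <- histogram_rc(blk, bin_width, c(lo, hi))
    Wb <- ifelse(h$density > 0, -thermo$RT * log(h$density), NA_real_)
    if (is.null(Wmat)) {
      Wmat <- matrix(NA_real_, nrow = n_blocks, ncol = length(Wb))
      mids <- h$mid
    }
    Wmat[b, ] <- Wb
  }
  err <- apply(Wmat, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) return(NA_real_)
    sd(col) / sqrt(length(col))
  })
  tibble(Rc = mids, err = err)
}

#' Barrier between two free-energy wells
#'
#' Locates the minimum of W inside each well range and reports the crossing
#' cost from the shallower (higher) well: the maximum of W on the sampled
#' span between the two minima, minus W at the higher minimum.
#'
#' @param profile A `fep` tibble.
#' @param well_a,well_b Length-2 R_c ranges (Angstrom) bracketing the two
#'   wells; must be disjoint and contain sampled bins.
#' @return A one-row tibble: `barrier` (kcal/mol), `rc_a`, `w_a`, `rc_b`,
#'   `w_b` (well positions/values), `rc_top`, `w_top` (barrier top).
#' @export
barrier_height <- function(profile, well_a, well_b) {
  if (max(well_a) > min(well_b)) {
    if (max(well_b) > min(well_a)) abort("Well ranges must be disjoint.")
    tmp <- well_a; well_a <- well_b; well_b <- tmp
  }
  sampled <- is.finite(profile$W)
  pick <- function(rng) {
    in_r <- sampled & profile$Rc >= rng[1] & profile$Rc <= rng[2]
    if (!any(in_r)) abort("A well range contains no sampled bins.")
    i <- which(in_r)[which.min(profile$W[in_r])]
    c(Rc = profile$Rc[i], W = profile$W[i])
  }
  a <- pick(well_a); b <- pick(well_b)
  between <- sampled & profile$Rc >= a[["Rc"]] & profile$Rc <= b[["Rc"]]
  if (!any(between)) abort("No sampled bins between the two wells.")
  itop <- which(between)[which.max(profile$W[between])]
  w_ref <- max(a[["W"]], b[["W"]])
  tibble(
    barrier = profile$W[itop] - w_ref,
    rc_a = a[["Rc"]], w_a = a[["W"]],
    rc_b = b[["Rc"]], w_b = b[["W"]],
    rc_top = profile$Rc[itop], w_top = profile$W[itop]
  )
}

#' @export
#' @method tidy fep
#' @rdname fep-tidiers
tidy.fep <- function(x, ...) {
  tibble(Rc = x$Rc, W = x$W, err = x$err, n = x$n, sampled = is.finite(x$W))
}

#' Tidiers for free-energy profiles
#'
#' `tidy()` returns the per-bin profile; `glance()` returns a one-row
#' summary (temperature, bin width, sample count, W range, WHAM
#' convergence when applicable).
#'
#' @param x A `fep` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method glance fep
#' @rdname fep-tidiers
glance.fep <- function(x, ...) {
  th <- attr(x, "thermo")
  cv <- attr(x, "convergence")
  tibble(
    temperature = th$temperature,
    bin_width = attr(x, "bin_width"),
    n_samples = sum(x$n),
    n_bins_sampled = sum(is.finite(x$W)),
    w_max = max(x$W, na.rm = TRUE),
    iterations = if (is.null(cv)) NA_integer_ else cv$iterations,
    residual = if (is.null(cv)) NA_real_ else cv$residual
  )
}

#' Plot a free-energy profile
#'
#' @param object A `fep` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot fep
autoplot.fep <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$sampled, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Rc, y = .data$W)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(R[c] ~ "(Å)"),
                  y = expression(W(R[c]) ~ "(kcal/mol)"))
  if (any(is.finite(df$err))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$W - .data$err, ymax = .data$W + .data$err),
      width = 0, colour = "grey50"
    )
  }
  p
}
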