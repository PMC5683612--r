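## Weighted histogram analysis method (WHAM) for umbrella-sampling windows
## along a scalar centre-of-mass distance coordinate, with Bayesian
## bootstrap error bars over complete window histograms.

#' Construct an umbrella-sampling window
#'
#' @param center harmonic bias centre r0 (nm).
#' @param k spring constant (kJ mol^-1 nm^-2); 0 means unbiased.
#' @param samples reaction-coordinate samples r_t (nm), non-negative.
#' @param dt sampling interval (ps), metadata only.
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, samples, dt = NA_real_) {
  .assert(is.numeric(center) && length(center) == 1 && center >= 0,
          "center must be a non-negative scalar (nm)")
  .assert(is.numeric(k) && length(k) == 1 && k >= 0, "k must be >= 0")
  .assert(length(samples) > 0 && all(is.finite(samples)) && all(samples >= 0),
          "samples must be non-empty, finite and >= 0")
  structure(list(center = center, k = k, samples = as.numeric(samples), dt = dt),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("umbrella_window: r0 = %g nm, k = %g kJ/mol/nm^2, %d samples\n",
              x$center, x$k, length(x$samples)))
  invisible(x)
}

#' Construct a PMF profile
#'
#' @param r bin centres (nm), strictly increasing, uniformly spaced.
#' @param G free energy G(r) (kJ/mol); `NA` marks bins with no samples.
#' @param temperature temperature (K).
#' @param std optional per-bin bootstrap standard deviation (kJ/mol).
#' @param counts optional per-bin total sample counts.
#' @return object of class `pmf_profile` carrying the (uniform) bin width.
#' @export
pmf_profile <- function(r, G, temperature, std = NULL, counts = NULL) {
  .assert(length(r) >= 2 && all(diff(r) > 0), "bin centres must be increasing")
  dr <- diff(r)
  .assert(max(abs(dr - dr[1])) < 1e-9 * dr[1], "bin centres must be uniform")
  .assert(length(G) == length(r), "length mismatch between r and G")
  .assert(all(is.finite(G) | is.na(G)), "G must be finite or NA")
  if (!is.null(std)) .assert(all(std >= 0, na.rm = TRUE), "std must be >= 0")
  structure(list(r = as.numeric(r), G = as.numeric(G),
                 std = std, counts = counts,
                 temperature = temperature, dr = dr[1]),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- !is.na(x$G)
  cat(sprintf("pmf_profile: %d bins (%.3g-%.3g nm, width %.3g), %d defined, T = %g K\n",
              length(x$r), min(x$r), max(x$r), x$dr, sum(ok), x$temperature))
  if (any(ok))
    cat(sprintf("  G range: %.3f to %.3f kJ/mol\n", min(x$G[ok]), max(x$G[ok])))
  invisible(x)
}

## core self-consistency loop on precomputed histograms.
## counts: windows x bins matrix; bias: windows x bins bias energies at bin
## centres; N: per-window (possibly weighted) sample totals.
.wham_core <- function(counts, bias, N, RT, tol, max_iter, f_init = NULL) {
  nw <- nrow(counts)
  f <- f_init %||% rep(0, nw)
  nb_tot <- colSums(counts)
  expb <- exp(-bias / RT)              # windows x bins
  for (it in seq_len(max_iter)) {
    denom <- colSums(N * exp(f / RT) * expb)   # per bin
    p <- ifelse(denom > 0, nb_tot / denom, 0)
    fz <- -RT * log(expb %*% p)
    fnew <- as.numeric(fz - fz[1])             # gauge: f_1 = 0
    delta <- max(abs(fnew - f)) / RT
    f <- fnew
    if (delta < tol)
      return(list(p = p, f = f, iterations = it, residual = delta))
  }
  stop(sprintf("WHAM did not converge in %d iterations (last residual %.3g)",
               max_iter, delta), call. = FALSE)
}

.window_histograms <- function(windows, edges) {
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- t(vapply(windows, function(w) {
    h <- graphics::hist(w$samples, breaks = edges, plot = FALSE, right = FALSE)
    h$counts
  }, numeric(length(centers))))
  bias <- t(vapply(windows, function(w) w$k / 2 * (centers - w$center)^2,
                   numeric(length(centers))))
  list(centers = centers, counts = counts, bias = bias)
}

.make_edges <- function(windows, bin_width, bin_edges) {
  if (!is.null(bin_edges)) {
    .assert(length(bin_edges) >= 2 && all(diff(bin_edges) > 0),
            "bin_edges must be increasing")
    return(bin_edges)
  }
  lo <- min(vapply(windows, function(w) min(w$samples), numeric(1)))
  hi <- max(vapply(windows, function(w) max(w$samples), numeric(1)))
  lo <- floor(lo / bin_width) * bin_width
  n <- ceiling((hi - lo) / bin_width + 1e-9)
  lo + bin_width * 0:max(n, 1)
}

#' Estimate a PMF from umbrella windows by WHAM
#'
#' Iterates the standard WHAM self-consistency equations — histogram
#' reweighting with per-window free-energy constants f_i — until the
#' maximum change in f_i per RT drops below `tol`.  The profile
#' `G(r) = -RT log(unbiased density)` is reported up to an additive
#' constant, defined only on bins that received at least one sample.  No
#' radial Jacobian is applied; the two-dimensional geometry enters later
#' through the explicit `pi * integral(r ...)` of [association_constant()].
#'
#' @param windows list of [umbrella_window()] objects.
#' @param bin_width histogram bin width (nm), default 0.01.
#' @param bin_edges optional explicit bin edges (overrides `bin_width`).
#' @param temperature temperature (K), default 303.
#' @param tol convergence tolerance on `max |delta f_i| / RT`.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last residual.
#' @return a [pmf_profile()]; window constants f_i are kept in attribute
#'   `"f"`, iteration count in `"iterations"`.
#' @export
wham <- function(windows, bin_width = 0.01, bin_edges = NULL,
                 temperature = 303, tol = 1e-7, max_iter = 1e5) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  .assert(length(windows) >= 1 &&
            all(vapply(windows, inherits, logical(1), "umbrella_window")),
          "windows must be umbrella_window objects")
  .assert(temperature > 0, "temperature must be > 0")
  edges <- .make_edges(windows, bin_width, bin_edges)
  h <- .window_histograms(windows, edges)
  .assert(any(colSums(h$counts) > 0), "no samples fall in any bin")
  RT <- rt(temperature)
  N <- vapply(windows, function(w) length(w$samples), numeric(1))
  sol <- .wham_core(h$counts, h$bias, N, RT, tol, max_iter)
  dens <- sol$p / sum(sol$p)
  G <- ifelse(dens > 0, -RT * log(dens), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  out <- pmf_profile(h$centers, G, temperature, counts = colSums(h$counts))
  attr(out, "f") <- sol$f
  attr(out, "iterations") <- sol$iterations
  out
}

#' Bootstrap error bars for a WHAM profile
#'
#' Bayesian bootstrap over complete window histograms: each replicate
#' re-solves WHAM with the windows' sample counts multiplied by random
#' exponential weights (normalized to preserve the total), which respects
#' the within-window autocorrelation that an independent-sample resampling
#' would ignore.  Replicates are shift-aligned to the full-data profile by
#' their mean offset over commonly defined bins before the per-bin standard
#' deviation is taken, so the result does not depend on the additive
#' convention.
#'
#' @inheritParams wham
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed optional integer seed; results are reproducible given it.
#' @return the full-data [pmf_profile()] with `$std` filled in; the aligned
#'   replicate profiles (matrix `n_boot` x bins, failed rows dropped) are in
#'   attribute `"replicates"`, the raw unaligned ones in `"replicates_raw"`,
#'   and the number of non-converged replicates in `"n_failed"` (a warning
#'   is raised when any fail).
#' @export
bootstrap_pmf <- function(windows, n_boot = 100, seed = NULL,
                          bin_width = 0.01, bin_edges = NULL,
                          temperature = 303, tol = 1e-7, max_iter = 1e5) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  .assert(n_boot >= 1, "n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  full <- wham(windows, bin_width, bin_edges, temperature, tol, max_iter)
  edges <- .make_edges(windows, bin_width, bin_edges)
  h <- .window_histograms(windows, edges)
  RT <- rt(temperature)
  N <- vapply(windows, function(w) length(w$samples), numeric(1))
  f0 <- attr(full, "f")
  nw <- length(windows)
  reps <- matrix(NA_real_, n_boot, length(full$r))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    w <- stats::rexp(nw)
    w <- w / sum(w) * nw
    sol <- tryCatch(
      .wham_core(h$counts * w, h$bias, N * w, RT, tol, max_iter, f_init = f0),
      error = function(e) NULL)
    if (is.null(sol)) { failed <- failed + 1L; next }
    dens <- sol$p / sum(sol$p)
    reps[b, ] <- ifelse(dens > 0, -RT * log(dens), NA_real_)
  }
  if (failed > 0)
    warning(sprintf("%d of %d bootstrap replicates did not converge and were excluded",
                    failed, n_boot), call. = FALSE)
  reps_raw <- reps[stats::complete.cases(reps[, !is.na(full$G), drop = FALSE]) &
                     rowSums(!is.na(reps)) > 0, , drop = FALSE]
  aligned <- reps_raw
  for (i in seq_len(nrow(aligned))) {
    common <- !is.na(aligned[i, ]) & !is.na(full$G)
    aligned[i, ] <- aligned[i, ] - mean(aligned[i, common] - full$G[common])
  }
  std <- if (nrow(aligned) >= 2) apply(aligned, 2, stats::sd) else
    rep(0, length(full$r))  # a single replicate carries no spread
  full$std <- ifelse(is.na(full$G), NA_real_, std)
  attr(full, "replicates") <- aligned
  attr(full, "replicates_raw") <- reps_raw
  attr(full, "n_failed") <- failed
  full
}

#' Shift a PMF to zero at a reference distance
#'
#' Subtracts the linearly interpolated `G(r_ref)` from all bins so that the
#' profile is exactly zero at the reference; idempotent.
#'
#' @param profile a [pmf_profile()].
#' @param r_ref reference distance (nm), default 2.75, a distance at which
#'   dimerization profiles have reached their plateau.
#' @return the shifted profile.
#' @export
shift_to_zero <- function(profile, r_ref = 2.75) {
  .assert(inherits(profile, "pmf_profile"), "need a pmf_profile")
  ok <- which(!is.na(profile$G))
  .assert(length(ok) >= 2, "profile has fewer than two defined bins")
  rs <- profile$r[ok]
  .assert(r_ref >= rs[1] && r_ref <= rs[length(rs)],
          "r_ref = %g nm lies outside the defined region [%g, %g]",
          r_ref, rs[1], rs[length(rs)])
  below <- max(which(rs <= r_ref)); above <- min(which(rs >= r_ref))
  .assert(ok[above] - ok[below] <= 1,
          "G is undefined on the bins bracketing r_ref = %g nm", r_ref)
  g0 <- if (below == above) profile$G[ok[below]] else
    stats::approx(rs[c(below, above)], profile$G[ok[c(below, above)]],
                  xout = r_ref)$y
  profile$G <- profile$G - g0
  profile
}
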