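test_that("WHAM on a single unbiased window reduces to the log-histogram", {
  pmf <- make_double_well_pmf()
  w <- metropolis_umbrella_sampler(pmf, centers = 1.0, k = 0,
                                   n_samples = 4000, seed = 3)
  pr <- wham(w, bin_width = 0.05)
  edges <- seq(min(pr$r) - pr$dr / 2, max(pr$r) + pr$dr / 2 + 1e-9, by = pr$dr)
  h <- hist(w[[1]]$samples, breaks = edges, plot = FALSE, right = FALSE)
  Gh <- -rt(303) * log(h$counts / sum(h$counts))
  Gh <- Gh - min(Gh[is.finite(Gh)])
  ok <- !is.na(pr$G) & is.finite(Gh)
  expect_true(any(ok))
  expect_lt(max(abs(pr$G[ok] - Gh[ok])), 1e-10)
  # and the unbiased estimate tracks the generating free-energy curve within
  # shot noise inflated by the chain's integrated autocorrelation time
  sel <- ok & pr$counts >= 25
  dd <- pr$G[sel] - pmf(pr$r[sel]); dd <- dd - mean(dd)
  ac <- acf(w[[1]]$samples, lag.max = 500, plot = FALSE)$acf[-1]
  iact <- 1 + 2 * sum(ac[seq_len(max(which(ac > 0.05)))])
  se <- rt(303) / sqrt(pr$counts[sel] / iact)
  expect_true(all(abs(dd) <= pmax(3 * se, 0.5)))
})

test_that("WHAM is invariant to duplicating windows and to constant bias offsets", {
  pmf <- make_double_well_pmf()
  w <- metropolis_umbrella_sampler(pmf, centers = c(0.8, 1.2, 1.6), k = 100,
                                   n_samples = 2000, seed = 5)
  pr1 <- wham(w, bin_width = 0.02)
  pr2 <- wham(c(w, w), bin_width = 0.02)     # same data twice
  expect_equal(pr2$G, pr1$G, tolerance = 1e-6)
  expect_error(wham(list()), "umbrella_window")
  expect_error(wham(w, max_iter = 2), "converge")
})

test_that("double-well recovery holds across seeds", {
  pmf <- make_double_well_pmf()
  centers <- seq(0.6, 2.8, by = 0.2)
  for (seed in c(11, 12, 13)) {
    w <- metropolis_umbrella_sampler(pmf, centers, k = 400,
                                     n_samples = 20000, seed = seed)
    pr <- wham(w, temperature = 303)
    sel <- which(!is.na(pr$G) & pr$r >= min(centers) & pr$r <= max(centers))
    dd <- pr$G[sel] - pmf(pr$r[sel])
    dd <- dd - mean(dd)
    expect_lt(sqrt(mean(dd^2)), 0.3)
  }
})

test_that("shift_to_zero pins the reference and is idempotent", {
  r <- seq(0.05, 3.95, by = 0.1)
  flat <- pmf_profile(r, rep(4.2, length(r)), 303)
  expect_equal(shift_to_zero(flat)$G, rep(0, length(r)))
  lin <- pmf_profile(r, 2 * r, 303)
  sh <- shift_to_zero(lin, r_ref = 2.75)
  expect_equal(stats::approx(sh$r, sh$G, xout = 2.75)$y, 0)
  expect_equal(diff(sh$G), diff(lin$G))                     # slope unchanged
  expect_equal(shift_to_zero(sh, 2.75)$G, sh$G)             # idempotent
  expect_error(shift_to_zero(lin, r_ref = 5), "outside")
  gap <- pmf_profile(r, ifelse(abs(r - 2.75) < 0.2, NA, 2 * r), 303)
  expect_error(shift_to_zero(gap, 2.75), "bracketing")
})

test_that("bootstrap spread behaves with replicate count and sample size", {
  pmf <- make_double_well_pmf()
  centers <- seq(0.7, 2.3, by = 0.4)
  edges <- seq(0.4, 3.0, by = 0.02)                         # shared grid
  w <- metropolis_umbrella_sampler(pmf, centers, k = 200,
                                   n_samples = 1500, seed = 21)
  b <- bootstrap_pmf(w, n_boot = 100, seed = 9, bin_edges = edges)
  expect_equal(nrow(attr(b, "replicates")), 100)            # all converged
  expect_equal(attr(b, "n_failed"), 0)
  expect_true(all(b$std[!is.na(b$G)] >= 0))
  # reproducibility given the seed
  b2 <- bootstrap_pmf(w, n_boot = 100, seed = 9, bin_edges = edges)
  expect_equal(b2$std, b$std)
  # a single replicate carries no spread by convention
  b1 <- bootstrap_pmf(w, n_boot = 1, seed = 1, bin_edges = edges)
  expect_equal(unique(b1$std[!is.na(b1$G)]), 0)
  # more data per window -> smaller mean per-bin std
  w_big <- metropolis_umbrella_sampler(pmf, centers, k = 200,
                                       n_samples = 6000, seed = 21)
  b_big <- bootstrap_pmf(w_big, n_boot = 50, seed = 9, bin_edges = edges)
  common <- !is.na(b$G) & !is.na(b_big$G)
  expect_lt(mean(b_big$std[common]), mean(b$std[common]))
})

test_that("bootstrap std does not depend on the shift convention", {
  pmf <- make_double_well_pmf()
  w <- metropolis_umbrella_sampler(pmf, c(0.8, 1.2, 1.6), k = 100,
                                   n_samples = 1500, seed = 31)
  b <- bootstrap_pmf(w, n_boot = 40, seed = 2, bin_width = 0.02)
  shifted <- b
  shifted$G <- shifted$G + 7.5                              # different convention
  for (i in seq_len(nrow(attr(shifted, "replicates_raw"))))
    attr(shifted, "replicates_raw")[i, ] <-
      attr(shifted, "replicates_raw")[i, ] + 7.5
  sd_of <- function(x) {
    reps <- attr(x, "replicates_raw")
    ok <- !is.na(x$G)
    aligned <- t(apply(reps, 1, function(g) g - mean(g[ok] - x$G[ok], na.rm = TRUE)))
    apply(aligned, 2, sd)[ok]
  }
  expect_equal(sd_of(shifted), sd_of(b), tolerance = 1e-10)
})
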