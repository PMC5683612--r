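## Synthetic fixtures with known ground truth: a Martini-like interaction
## matrix, ideal coarse-grained helices and crossed dimers, Metropolis
## samples from a known PMF under harmonic bias, and COM configurations
## with a known cluster partition.  Every generator is deterministic given
## its seed.

## the nine-level well-depth ladder (kJ/mol), strongest first
.MARTINI_LADDER <- c(5.6, 5.0, 4.5, 4.0, 3.5, 3.1, 2.7, 2.3, 2.0)

#' Martini-like nonbonded interaction matrix
#'
#' Builds a completed symmetric fixture table over nine normal bead types
#' (four protein, one water, three lipid, one ion) using the nine-level
#' well-depth ladder from 2.0 to 5.6 kJ/mol.  All pairs use sigma =
#' 0.47 nm except the super-repulsive charged-apolar pairs at sigma =
#' 0.62 nm.  With `include_small = TRUE` each type gains a small/ring twin
#' (prefix "S", mass 45 amu): small-small pairs use sigma = 0.43 nm with
#' well depths reduced by 25 percent, small-normal pairs keep the normal
#' values.
#'
#' The seven intermediate ladder values are a fixture choice (the standard
#' ladder); only the endpoints, the sigma values and the 25 percent
#' small-bead reduction are anchored facts.
#'
#' @param levels the nine-level ladder, strongest first.
#' @param include_small add the small-bead block (default TRUE).
#' @return a completed [nonbond_table()]; per-type categories are in
#'   attribute `"categories"`, the ladder in `"ladder"`.
#' @export
martini_like_matrix <- function(levels = .MARTINI_LADDER, include_small = TRUE) {
  .assert(length(levels) == 9 && all(diff(levels) < 0),
          "need 9 strictly decreasing ladder levels")
  nm <- c("P5", "P4", "Qa", "Qd", "W", "Na", "C1", "C3", "Q0")
  cat_ <- c(P5 = "protein", P4 = "protein", Qa = "protein", Qd = "protein",
            W = "water", Na = "lipid", C1 = "lipid", C3 = "lipid", Q0 = "ion")
  chg <- c(P5 = 0, P4 = 0, Qa = -1, Qd = 1, W = 0, Na = 0, C1 = 0, C3 = 0, Q0 = 1)
  ## level indices into the ladder; 0 marks the super-repulsive pairs
  ## (weakest level with sigma = 0.62 nm).  The protein-protein block
  ## (first four types) covers all nine levels, so scaling the protein set
  ## exercises the full ladder.
  L <- matrix(c(
    1, 2, 3, 4, 1, 3, 9, 7, 2,
    2, 5, 6, 7, 2, 4, 9, 7, 3,
    3, 6, 8, 1, 2, 4, 0, 8, 1,
    4, 7, 1, 9, 2, 4, 0, 8, 1,
    1, 2, 2, 2, 2, 4, 9, 7, 2,
    3, 4, 4, 4, 4, 4, 6, 5, 4,
    9, 9, 0, 0, 9, 6, 3, 4, 0,
    7, 7, 8, 8, 7, 5, 4, 4, 8,
    2, 3, 1, 1, 2, 4, 0, 8, 2), 9, 9, byrow = TRUE,
    dimnames = list(nm, nm))
  .assert(identical(L, t(L)), "internal: level matrix must be symmetric")
  pairs <- list()
  for (a in 1:9) for (b in a:9) {
    lv <- L[a, b]
    pairs[[length(pairs) + 1]] <- data.frame(
      i = nm[a], j = nm[b],
      eps = if (lv == 0) levels[9] else levels[lv],
      sigma = if (lv == 0) 0.62 else 0.47)
  }
  types <- data.frame(name = nm, mass = 72, charge = unname(chg[nm]), small = FALSE)
  if (include_small) {
    snm <- paste0("S", nm)
    types <- rbind(types, data.frame(name = snm, mass = 45,
                                     charge = unname(chg[nm]), small = TRUE))
    for (a in 1:9) for (b in a:9) {        # small-small: 75% eps, sigma 0.43
      lv <- L[a, b]
      eps <- if (lv == 0) levels[9] else levels[lv]
      pairs[[length(pairs) + 1]] <- data.frame(i = snm[a], j = snm[b],
                                               eps = 0.75 * eps, sigma = 0.43)
    }
    for (a in 1:9) for (b in 1:9) {        # small-normal: normal values
      lv <- L[a, b]
      pairs[[length(pairs) + 1]] <- data.frame(
        i = snm[a], j = nm[b],
        eps = if (lv == 0) levels[9] else levels[lv],
        sigma = if (lv == 0) 0.62 else 0.47)
    }
    cat_ <- c(cat_, stats::setNames(unname(cat_[nm]), snm))
  }
  out <- nonbond_table(types, do.call(rbind, pairs))
  attr(out, "categories") <- cat_
  attr(out, "ladder") <- levels
  out
}

## rotation taking unit vector u onto unit vector v (Rodrigues)
.rotation_from_to <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {                   # antiparallel: rotate pi about any normal
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- p - sum(p * u) * u; a <- a / sqrt(sum(a^2))
    return(2 * outer(a, a) - diag(3))
  }
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Ideal coarse-grained helix
#'
#' Backbone beads on a regular helix (standard alpha-helical defaults:
#' 0.15 nm rise and 100 degree twist per residue, 0.23 nm radius).  The
#' construction is de-tilted so that the principal axis of the bead set
#' equals the requested axis to machine precision, with the sign pointing
#' from the first towards the last residue.
#'
#' @param n_res number of residues (>= 3).
#' @param rise rise per residue (nm).
#' @param twist twist per residue (degrees).
#' @param radius helix radius (nm); 0 gives collinear beads on the axis.
#' @param axis desired principal-axis direction (need not be unit length).
#' @param origin centroid position of the bead set (nm).
#' @param peptide peptide id.
#' @return a [peptide_backbone()].
#' @export
ideal_helix <- function(n_res, rise = 0.15, twist = 100, radius = 0.23,
                        axis = c(0, 0, 1), origin = c(0, 0, 0), peptide = 1L) {
  .assert(n_res >= 3, "need n_res >= 3")
  .assert(sum(axis^2) > 1e-20, "degenerate axis")
  k <- seq_len(n_res) - 1
  th <- k * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), k * rise)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  if (radius > 0) {                         # de-tilt onto exact z
    a0 <- principal_axis(xyz)
    xyz <- xyz %*% t(.rotation_from_to(a0, c(0, 0, 1)))
  }
  R <- .rotation_from_to(c(0, 0, 1), axis)
  xyz <- sweep(xyz %*% t(R), 2, origin, "+")
  peptide_backbone(xyz, peptide = peptide)
}

#' Crossed dimer with known crossing angle
#'
#' Two ideal helices whose principal axes subtend exactly the requested
#' angle, at the requested closest-approach separation (the axes lie in
#' parallel x-z planes offset along y).
#'
#' @param angle crossing angle in degrees, in `[0, 90]`.
#' @param separation closest-approach distance between the axes (nm).
#' @param n_res residues per helix.
#' @param box box lengths (nm); default comfortably larger than the dimer.
#' @param ... further arguments passed to [ideal_helix()].
#' @return a [dimer_frame()]; the constructed angle is in attribute
#'   `"angle"`.
#' @export
make_crossed_dimer <- function(angle, separation = 0.8, n_res = 26,
                               box = c(30, 30, 30), ...) {
  .assert(angle >= 0 && angle <= 90, "angle must be in [0, 90] degrees")
  half <- angle / 2 * pi / 180
  u1 <- c(sin(half), 0, cos(half))
  u2 <- c(-sin(half), 0, cos(half))
  ctr <- box / 2
  p1 <- ideal_helix(n_res, axis = u1, origin = ctr + c(0, -separation / 2, 0),
                    peptide = 1L, ...)
  p2 <- ideal_helix(n_res, axis = u2, origin = ctr + c(0, separation / 2, 0),
                    peptide = 2L, ...)
  out <- dimer_frame(p1, p2, box = box)
  attr(out, "angle") <- angle
  out
}

#' Double-well model PMF
#'
#' A smooth free-energy curve with a soft repulsive wall, a deep contact
#' well and a shallower secondary well, decaying to zero beyond 2 nm —
#' ground truth for exercising the umbrella-sampling/WHAM/association
#' pipeline end to end.
#'
#' @param depth1,depth2 well depths (kJ/mol, positive numbers).
#' @param r1,r2 well positions (nm).
#' @param width Gaussian well width (nm).
#' @param wall_height,wall_r0,wall_decay exponential wall parameters.
#' @param domain sampling domain (nm).
#' @return function `G(r)` (kJ/mol) of class `true_pmf` with the domain in
#'   attribute `"domain"`.
#' @export
make_double_well_pmf <- function(depth1 = 8, depth2 = 3, r1 = 0.85, r2 = 1.45,
                                 width = 0.18, wall_height = 25, wall_r0 = 0.45,
                                 wall_decay = 0.06, domain = c(0.45, 3.2)) {
  f <- function(r) {
    wall_height * exp(-(r - wall_r0) / wall_decay) -
      depth1 * exp(-((r - r1) / width)^2) -
      depth2 * exp(-((r - r2) / width)^2)
  }
  attr(f, "domain") <- domain
  class(f) <- c("true_pmf", "function")
  f
}

#' Metropolis sampler for biased umbrella windows
#'
#' Draws Markov-chain samples from the biased Boltzmann density
#' `exp(-(G_true(r) + k/2 (r - r0)^2) / RT)` for each window centre, by
#' random-walk Metropolis with the step size auto-tuned to a 30-60 percent
#' acceptance rate; the leading 10 percent of each chain is discarded as
#' burn-in.  Fully reproducible given `seed`.
#'
#' @param true_pmf a `true_pmf` function (see [make_double_well_pmf()]) or
#'   any function of r with a `"domain"` attribute.
#' @param centers window centres r0 (nm), within the PMF domain.
#' @param k spring constant (kJ mol^-1 nm^-2), default 400.
#' @param n_samples retained samples per window.
#' @param temperature temperature (K), default 303.
#' @param seed optional integer seed.
#' @return list of [umbrella_window()] objects; per-window acceptance rates
#'   are in attribute `"acceptance"`.
#' @export
metropolis_umbrella_sampler <- function(true_pmf, centers, k = 400,
                                        n_samples = 1000, temperature = 303,
                                        seed = NULL) {
  dom <- attr(true_pmf, "domain")
  .assert(!is.null(dom) && length(dom) == 2, "true_pmf needs a 'domain' attribute")
  .assert(all(centers >= dom[1] & centers <= dom[2]),
          "window centres must lie within the PMF domain [%g, %g]", dom[1], dom[2])
  .assert(n_samples >= 1, "n_samples must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  RT <- rt(temperature)
  logdens <- function(r, r0) -(true_pmf(r) + k / 2 * (r - r0)^2) / RT
  windows <- vector("list", length(centers))
  acc_rates <- numeric(length(centers))
  for (wi in seq_along(centers)) {
    r0 <- centers[wi]
    step <- if (k > 0) 2.4 * sqrt(RT / k) else 0.1 * diff(dom)
    ## tune the proposal width on short pilot chains
    x <- min(max(r0, dom[1]), dom[2])
    for (round in 1:12) {
      acc <- 0L
      for (i in 1:200) {
        prop <- x + stats::runif(1, -step, step)
        if (prop >= dom[1] && prop <= dom[2] &&
            log(stats::runif(1)) < logdens(prop, r0) - logdens(x, r0)) {
          x <- prop; acc <- acc + 1L
        }
      }
      rate <- acc / 200
      if (rate < 0.30) step <- step * 0.7
      else if (rate > 0.60) step <- step * 1.4
      else break
    }
    nburn <- max(1L, ceiling(0.1 * n_samples))
    ntot <- n_samples + nburn
    out <- numeric(ntot)
    lx <- logdens(x, r0)
    jumps <- stats::runif(ntot, -step, step)
    lu <- log(stats::runif(ntot))
    acc <- 0L
    for (i in seq_len(ntot)) {
      prop <- x + jumps[i]
      if (prop >= dom[1] && prop <= dom[2]) {
        lp <- logdens(prop, r0)
        if (lu[i] < lp - lx) { x <- prop; lx <- lp; acc <- acc + 1L }
      }
      out[i] <- x
    }
    acc_rates[wi] <- acc / ntot
    windows[[wi]] <- umbrella_window(r0, k, out[(nburn + 1):ntot])
  }
  .assert(all(is.finite(acc_rates)), "sampler failed: zero density everywhere")
  attr(windows, "acceptance") <- acc_rates
  windows
}

#' COM configuration with known cluster partition
#'
#' Places clusters of the requested sizes as tightly chained groups
#' (member spacing safely below the cutoff) on a grid with inter-cluster
#' gaps safely above it, jittered reproducibly, so that single-linkage
#' clustering at the stated cutoff recovers the requested partition
#' exactly.  All points keep more than half a cutoff of clearance from the
#' box faces, so periodic images cannot bridge clusters.
#'
#' @param n total number of peptides.
#' @param cluster_spec integer cluster sizes summing to `n`.
#' @param box box lengths (nm).
#' @param seed optional integer seed for the jitter.
#' @param cutoff linkage cutoff (nm) the construction targets, default 2.5.
#' @return list with `coms` (n x 3 matrix), `labels` (expected partition,
#'   lowest-member-index convention), `sizes`, `box`, `cutoff`.
#' @export
make_oligomer_config <- function(n, cluster_spec, box = c(40, 40, 10),
                                 seed = NULL, cutoff = 2.5) {
  .assert(sum(cluster_spec) == n && all(cluster_spec >= 1),
          "cluster sizes must be positive and sum to n")
  .check_box(box)
  if (!is.null(seed)) set.seed(seed)
  spacing <- 0.8 * cutoff
  gap <- 1.5 * cutoff
  margin <- cutoff / 2 + 0.2
  extent <- (max(cluster_spec) - 1) * spacing
  pitch_x <- extent + gap
  ncol_ <- max(1, floor((box[1] - 2 * margin) / pitch_x))
  nrow_ <- ceiling(length(cluster_spec) / ncol_)
  .assert(margin + (nrow_ - 1) * gap <= box[2] - margin &&
            pitch_x <= box[1] - 2 * margin + 1e-9 && box[3] >= 2 * margin,
          "infeasible packing: box too small for %d clusters at cutoff %g",
          length(cluster_spec), cutoff)
  coms <- matrix(NA_real_, n, 3)
  labels <- integer(n)
  idx <- 1L
  for (ci in seq_along(cluster_spec)) {
    row <- (ci - 1) %/% ncol_
    col <- (ci - 1) %% ncol_
    ox <- margin + col * pitch_x
    oy <- margin + row * gap
    first <- idx
    for (m in seq_len(cluster_spec[ci])) {
      jit <- stats::runif(3, -0.05, 0.05) * spacing
      coms[idx, ] <- c(ox + (m - 1) * spacing, oy, box[3] / 2) + jit
      labels[idx] <- first
      idx <- idx + 1L
    }
  }
  list(coms = coms, labels = labels, sizes = as.integer(cluster_spec),
       box = box, cutoff = cutoff)
}
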