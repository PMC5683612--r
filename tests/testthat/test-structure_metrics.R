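rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

test_that("Kabsch superposition recovers rigid transforms and proper rotations", {
  set.seed(6)
  x <- matrix(rnorm(30), 10, 3)
  self <- kabsch_superpose(x, x)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-10)
  R <- rot_z(37)
  moved <- sweep(x %*% t(R), 2, c(1, -2, 0.5), "+")
  fit <- kabsch_superpose(moved, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-8)   # inverse recovered
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # near-reflection input still yields a proper rotation
  mirror <- x %*% diag(c(1, 1, -1))
  expect_equal(det(kabsch_superpose(mirror, x)$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(x[1:4, ], x), "counts differ")
  # agreement with an independent least-squares fit on random pairs
  for (seed in 1:3) {
    set.seed(seed)
    a <- matrix(rnorm(24), 8, 3); b <- matrix(rnorm(24), 8, 3)
    ours <- kabsch_superpose(a, b)
    theirs <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.numeric(t(b)), mobile = as.numeric(t(a))))
    ref_rmsd <- sqrt(mean(rowSums((matrix(theirs, ncol = 3, byrow = TRUE) - b)^2)))
    expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
  }
})

test_that("principal axis follows the spread and the first-to-last sign rule", {
  line_z <- cbind(0, 0, seq(0, 2, length.out = 8))
  expect_equal(principal_axis(line_z), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(principal_axis(line_z[8:1, ]), c(0, 0, -1), tolerance = 1e-12)
  helix <- ideal_helix(26, axis = c(0, 0, 1))
  expect_equal(principal_axis(helix), c(0, 0, 1), tolerance = 1e-6)
  tilted <- ideal_helix(20, axis = c(1, 1, 1))
  expect_equal(principal_axis(tilted), rep(1 / sqrt(3), 3), tolerance = 1e-6)
  expect_error(principal_axis(matrix(0, 5, 3)), "coincident")
  expect_error(principal_axis(line_z[1:2, ]), "at least 3")
})

test_that("crossing angle recovers constructed geometries and is symmetric", {
  for (ang in c(0, 15, 40, 63.5, 90)) {
    d <- make_crossed_dimer(ang)
    expect_equal(crossing_angle(d), ang, tolerance = 1e-6)
    swapped <- dimer_frame(d$pep2, d$pep1, d$box)
    expect_equal(crossing_angle(swapped), crossing_angle(d), tolerance = 1e-9)
  }
  expect_error(make_crossed_dimer(120), "\\[0, 90\\]")
  # restricted residue ranges: bend the tail of one helix, the contact-helix
  # range still reports the constructed angle
  d <- make_crossed_dimer(30, n_res = 30)
  bent <- d$pep1$xyz
  bent[25:30, 1] <- bent[25:30, 1] + seq(0.3, 1.8, length.out = 6)
  db <- dimer_frame(peptide_backbone(bent), d$pep2, d$box)
  full <- crossing_angle(db)
  ranged <- crossing_angle(db, range1 = c(1, 20), range2 = c(1, 30))
  expect_gt(abs(full - 30), abs(ranged - 30))
  expect_equal(ranged, 30, tolerance = 0.5)
})

test_that("metrics are invariant under global rigid motion", {
  d <- make_crossed_dimer(40, separation = 0.9)
  ref <- dimer_reference(d$pep1, d$pep2)
  move <- function(p) peptide_backbone(
    sweep(p$xyz %*% t(rot_z(77)), 2, c(3, -1, 2), "+"), p$resid, p$peptide)
  d2 <- dimer_frame(move(d$pep1), move(d$pep2), box = NULL)
  expect_equal(crossing_angle(d2), crossing_angle(d), tolerance = 1e-9)
  expect_equal(interpeptide_contacts(d2), interpeptide_contacts(d))
  expect_equal(backbone_rmsd(d2, ref), 0, tolerance = 1e-10)
})

test_that("dimer RMSD minimizes over chain pairings and beats no superposition", {
  d <- make_crossed_dimer(25, separation = 0.9)
  ref <- dimer_reference(d$pep1, d$pep2)
  expect_equal(backbone_rmsd(d, ref), 0, tolerance = 1e-12)
  # homodimer chains swapped relative to the reference: still zero
  expect_equal(backbone_rmsd(dimer_frame(d$pep2, d$pep1, d$box), ref), 0,
               tolerance = 1e-10)
  # distorted frame: superposed RMSD <= raw RMSD
  noisy <- d$pep2$xyz + matrix(runif(length(d$pep2$xyz), -0.3, 0.3),
                               ncol = 3)
  dn <- dimer_frame(d$pep1, peptide_backbone(noisy), d$box)
  raw <- sqrt(mean(rowSums((rbind(dn$pep1$xyz, dn$pep2$xyz) -
                              rbind(ref$pep1$xyz, ref$pep2$xyz))^2)))
  expect_lte(backbone_rmsd(dn, ref), raw + 1e-12)
})

test_that("contact counts equal the brute-force loop on random fixtures", {
  set.seed(77)
  for (trial in 1:1000) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    box <- if (trial %% 2 == 0) runif(3, 3, 6) else NULL
    span <- if (is.null(box)) c(4, 4, 4) else box
    a <- cbind(runif(n1, 0, span[1]), runif(n1, 0, span[2]), runif(n1, 0, span[3]))
    b <- cbind(runif(n2, 0, span[1]), runif(n2, 0, span[2]), runif(n2, 0, span[3]))
    cutoff <- runif(1, 0.5, 1.5)
    fr <- dimer_frame(peptide_backbone(a), peptide_backbone(b), box)
    expect_identical(interpeptide_contacts(fr, cutoff),
                     brute_contacts(a, b, cutoff, box))
  }
  # closed boundary: a pair at exactly the cutoff counts
  p1 <- peptide_backbone(rbind(c(0, 0, 0), c(0, 0, 0.3), c(0, 0, 0.6)))
  p2 <- peptide_backbone(rbind(c(0.8, 0, 0), c(5, 5, 5), c(6, 6, 6)))
  expect_identical(interpeptide_contacts(dimer_frame(p1, p2, c(20, 20, 20)), 0.8), 1L)
})

test_that("deviation summary averages the three criteria over the window", {
  ref_d <- make_crossed_dimer(40, separation = 0.9)
  ref <- dimer_reference(ref_d$pep1, ref_d$pep2)
  # trajectory = reference repeated: all deviations zero
  still <- rep(list(ref_d), 6)
  s0 <- dimer_deviation_summary(still, ref, last_fraction = 0.5)
  expect_equal(s0$n_frames, 3)                           # windowing
  expect_equal(c(s0$mean_rmsd, s0$mean_dangle, s0$mean_dcontacts), c(0, 0, 0),
               tolerance = 1e-9)
  # alternating two known conformations: means equal two-point averages
  alt_d <- make_crossed_dimer(55, separation = 1.2)
  traj <- rep(list(ref_d, alt_d), 4)
  s <- dimer_deviation_summary(traj, ref, last_fraction = 1)
  one <- function(f) c(backbone_rmsd(f, ref),
                       abs(crossing_angle(f, ref$range1, ref$range2) - ref$crossing),
                       interpeptide_contacts(f) - ref$n_contacts)
  expected <- (one(ref_d) + one(alt_d)) / 2
  expect_equal(c(s$mean_rmsd, s$mean_dangle, s$mean_dcontacts), expected,
               tolerance = 1e-9)
  rs <- replica_deviation_summary(list(still, traj), ref, last_fraction = 1)
  expect_equal(nrow(rs), 3)
  expect_equal(rs$mean_dangle[3], mean(rs$mean_dangle[1:2]))
  expect_true(acceptable_dimer(0.4, 8))
  expect_false(acceptable_dimer(0.4, 12))
  expect_false(acceptable_dimer(1.2, 8))
})

test_that("Calpha mapping and motif alignment anchor the first peptide", {
  ca <- sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                1:8, rep(c("A", "B"), each = 4), rep(1:4, 2),
                c(0, 1.5, 3, 4.5, 10, 11.5, 13, 14.5),
                c(0, 1, 0, 1, 5, 6, 5, 6), (1:8) * 2)
  cb <- sprintf("ATOM  %5d  CB  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                101:108, rep(c("A", "B"), each = 4), rep(1:4, 2),
                c(0, 1.5, 3, 4.5, 10, 11.5, 13, 14.5),
                c(0, 1, 0, 1, 5, 6, 5, 6) + 1, (1:8) * 2)
  pdb <- c("CRYST1   80.000   80.000   80.000  90.00  90.00  90.00 P 1",
           ca, cb)
  bb <- map_atomistic_to_cg_backbone(pdb, chain = "A")
  expect_equal(nrow(bb$xyz), 4)                          # one bead per residue
  expect_equal(bb$xyz[2, ], c(0.15, 0.1, 0.4))           # Angstrom -> nm
  bb2 <- map_atomistic_to_cg_backbone(pdb, chain = "B")
  expect_false(bb$peptide == bb2$peptide)
  no_ca <- pdb[-3]                                       # residue 2 keeps only CB
  expect_error(map_atomistic_to_cg_backbone(no_ca, chain = "A"), "residue")

  d <- make_crossed_dimer(35)
  ref <- dimer_reference(d$pep1, d$pep2, motif_range = c(5, 15))
  move <- function(p) peptide_backbone(
    sweep(p$xyz %*% t(rot_z(120)), 2, c(-4, 2, 1), "+"), p$resid, p$peptide)
  displaced <- dimer_frame(move(d$pep1), move(d$pep2))
  back <- motif_align(displaced, ref)
  expect_equal(back$pep1$xyz, d$pep1$xyz, tolerance = 1e-8)
  expect_equal(back$pep2$xyz, d$pep2$xyz, tolerance = 1e-8)
})
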