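## Dimer structure-quality metrics against a coarse-grained reference:
## joint-backbone RMSD after Kabsch superposition, helix crossing angle
## from principal axes, and inter-peptide backbone contact counts.

#' Construct a peptide backbone
#'
#' @param xyz ordered backbone bead coordinates (nm, n x 3).
#' @param resid residue ids (1-based, strictly increasing); defaults to
#'   `1:n`.
#' @param peptide peptide id (scalar).
#' @return object of class `peptide_backbone`.
#' @export
peptide_backbone <- function(xyz, resid = NULL, peptide = 1L) {
  xyz <- rbind(xyz)
  .assert(ncol(xyz) == 3 && all(is.finite(xyz)), "xyz must be finite n x 3")
  .assert(nrow(xyz) >= 3, "need at least 3 backbone beads")
  resid <- resid %||% seq_len(nrow(xyz))
  .assert(length(resid) == nrow(xyz) && all(diff(resid) > 0),
          "resid must be strictly increasing, one per bead")
  structure(list(xyz = unname(xyz), resid = as.integer(resid),
                 peptide = as.integer(peptide)),
            class = "peptide_backbone")
}

#' Construct a two-peptide dimer frame
#'
#' @param pep1,pep2 [peptide_backbone()] objects.
#' @param box orthorhombic box lengths (nm) or NULL for a non-periodic
#'   frame.
#' @return object of class `dimer_frame`.
#' @export
dimer_frame <- function(pep1, pep2, box = NULL) {
  .assert(inherits(pep1, "peptide_backbone") && inherits(pep2, "peptide_backbone"),
          "pep1/pep2 must be peptide_backbone objects")
  .check_box(box)
  structure(list(pep1 = pep1, pep2 = pep2, box = box), class = "dimer_frame")
}

#' Construct a dimer reference structure
#'
#' Holds the coarse-grained reference dimer (e.g. a Calpha-mapped NMR
#' model) together with the contact-helix residue ranges used for the
#' crossing angle, the reference angle and contact count (computed from
#' the structure when not given), and an optional dimerization-motif range
#' on peptide 1 for motif-based alignment.
#'
#' @param pep1,pep2 [peptide_backbone()] objects.
#' @param range1,range2 contact-helix residue ranges `c(first, last)`;
#'   default to the full chains.
#' @param crossing reference crossing angle (degrees, in `[0, 90]`);
#'   computed from the structure when NULL.
#' @param n_contacts reference inter-peptide backbone contact count;
#'   computed from the structure when NULL.
#' @param motif_range optional dimerization-motif residue range on pep1.
#' @param contact_cutoff cutoff (nm) used when computing `n_contacts`.
#' @return object of class `dimer_reference`.
#' @export
dimer_reference <- function(pep1, pep2, range1 = NULL, range2 = NULL,
                            crossing = NULL, n_contacts = NULL,
                            motif_range = NULL, contact_cutoff = 0.8) {
  range1 <- range1 %||% range(pep1$resid)
  range2 <- range2 %||% range(pep2$resid)
  .assert(range1[1] >= min(pep1$resid) && range1[2] <= max(pep1$resid) &&
            range2[1] >= min(pep2$resid) && range2[2] <= max(pep2$resid),
          "contact-helix range outside the residue span")
  if (!is.null(motif_range))
    .assert(motif_range[1] >= min(pep1$resid) && motif_range[2] <= max(pep1$resid),
            "motif range outside peptide 1")
  frame <- dimer_frame(pep1, pep2)
  crossing <- crossing %||% crossing_angle(frame, range1, range2)
  .assert(crossing >= 0 && crossing <= 90, "reference angle must be in [0, 90]")
  n_contacts <- n_contacts %||% interpeptide_contacts(frame, contact_cutoff)
  structure(list(pep1 = pep1, pep2 = pep2, range1 = range1, range2 = range2,
                 crossing = crossing, n_contacts = n_contacts,
                 motif_range = motif_range),
            class = "dimer_reference")
}

#' Extract per-peptide backbones from a coordinate frame
#'
#' Groups the protein beads of a [cg_frame()] by peptide id into
#' [peptide_backbone()] objects (one bead per stored protein bead, in
#' residue order) — the bridge from coordinate files to the dimer metrics.
#'
#' @param frame a [cg_frame()].
#' @return named list of [peptide_backbone()] objects.
#' @export
frame_backbones <- function(frame) {
  .assert(inherits(frame, "cg_frame"), "need a cg_frame")
  ip <- which(frame$category == "protein")
  .assert(length(ip) > 0, "frame has no protein beads")
  peps <- sort(unique(frame$peptide[ip]))
  out <- lapply(peps, function(p) {
    sel <- ip[frame$peptide[ip] == p]
    sel <- sel[order(frame$resid[sel])]
    peptide_backbone(frame$xyz[sel, , drop = FALSE], frame$resid[sel], p)
  })
  stats::setNames(out, paste0("peptide", peps))
}

#' Map an atomistic PDB chain to a coarse-grained backbone
#'
#' One bead per residue at the Calpha position, converted to nm — the
#' backbone part of the standard coarse-graining mapping.
#'
#' @param text PDB file path, string or lines.
#' @param chain chain identifier; NULL takes the first chain.
#' @return a [peptide_backbone()].
#' @export
map_atomistic_to_cg_backbone <- function(text, chain = NULL) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(.split_lines(text), tf)
  p <- bio3d::read.pdb(tf, verbose = FALSE)
  a <- p$atom
  chains <- unique(a$chain)
  chain <- chain %||% chains[1]
  .assert(chain %in% chains, "chain '%s' not found (have: %s)", chain,
          paste(chains, collapse = ", "))
  sel <- a[a$chain == chain & a$elety == "CA", ]
  sel <- sel[order(sel$resno), ]
  resall <- sort(unique(a$resno[a$chain == chain]))
  missing <- setdiff(resall, sel$resno)
  .assert(length(missing) == 0, "missing Calpha for residue(s): %s",
          paste(missing, collapse = ", "))
  peptide_backbone(cbind(sel$x, sel$y, sel$z) / 10, resid = sel$resno,
                   peptide = match(chain, chains))
}

#' Joint-backbone RMSD of a dimer frame against the reference
#'
#' Kabsch-superposes the concatenated backbones of both peptides onto the
#' reference and returns the minimized RMSD.  For frames whose two chains
#' have equal bead counts (homodimer ambiguity) the minimum over the two
#' chain pairings is taken.
#'
#' @param frame a [dimer_frame()].
#' @param ref a [dimer_reference()].
#' @return RMSD in nm.
#' @export
backbone_rmsd <- function(frame, ref) {
  refxyz <- rbind(ref$pep1$xyz, ref$pep2$xyz)
  pairings <- list(rbind(frame$pep1$xyz, frame$pep2$xyz))
  if (nrow(frame$pep1$xyz) == nrow(frame$pep2$xyz) &&
      nrow(ref$pep1$xyz) == nrow(ref$pep2$xyz))
    pairings <- c(pairings, list(rbind(frame$pep2$xyz, frame$pep1$xyz)))
  .assert(all(vapply(pairings, nrow, integer(1)) == nrow(refxyz)),
          "bead counts differ between frame (%d) and reference (%d)",
          nrow(pairings[[1]]), nrow(refxyz))
  min(vapply(pairings, function(m) kabsch_superpose(m, refxyz)$rmsd, numeric(1)))
}

#' Helix crossing angle of a dimer
#'
#' Angle between the principal axes of the two peptides computed over the
#' contact-helix residue ranges, folded by `acos(|u . v|)` into `[0, 90]`
#' degrees — handedness is ignored.
#'
#' @param frame a [dimer_frame()].
#' @param range1,range2 contact-helix residue ranges; default full chains.
#' @return crossing angle in degrees.
#' @export
crossing_angle <- function(frame, range1 = NULL, range2 = NULL) {
  u <- principal_axis(frame$pep1, range1)
  v <- principal_axis(frame$pep2, range2)
  acos(min(abs(sum(u * v)), 1)) * 180 / pi
}

#' Inter-peptide backbone contact count
#'
#' Number of backbone bead pairs, one bead from each peptide, within the
#' cutoff under the minimum-image convention.  The boundary is closed:
#' a pair at exactly the cutoff counts.
#'
#' @param frame a [dimer_frame()].
#' @param cutoff contact cutoff (nm), default 0.8.
#' @return integer contact count.
#' @export
interpeptide_contacts <- function(frame, cutoff = 0.8) {
  .assert(cutoff > 0, "cutoff must be > 0")
  if (is.null(frame$box)) {
    span <- apply(rbind(frame$pep1$xyz, frame$pep2$xyz), 2, function(x) diff(range(x)))
    .assert(all(is.finite(span)), "invalid coordinates")
  }
  d <- pair_distances(frame$pep1$xyz, frame$pep2$xyz, frame$box)
  sum(d <= cutoff)
}

#' Align a dimer frame on the reference dimerization motif
#'
#' Kabsch-fits the motif beads of peptide 1 onto the reference motif and
#' applies the resulting rigid transform to the whole dimer — the
#' motif-anchored view used to compare the placement of the second,
#' unfitted peptide.
#'
#' @param frame a [dimer_frame()].
#' @param ref a [dimer_reference()] with a `motif_range`.
#' @return the transformed [dimer_frame()].
#' @export
motif_align <- function(frame, ref) {
  .assert(!is.null(ref$motif_range), "reference has no motif_range")
  sel_f <- frame$pep1$resid >= ref$motif_range[1] & frame$pep1$resid <= ref$motif_range[2]
  sel_r <- ref$pep1$resid >= ref$motif_range[1] & ref$pep1$resid <= ref$motif_range[2]
  .assert(sum(sel_f) == sum(sel_r) && sum(sel_r) >= 3,
          "motif selections differ or are too small")
  fit <- kabsch_superpose(frame$pep1$xyz[sel_f, , drop = FALSE],
                          ref$pep1$xyz[sel_r, , drop = FALSE])
  move <- function(x) sweep(x %*% t(fit$rotation), 2, fit$translation, "+")
  dimer_frame(peptide_backbone(move(frame$pep1$xyz), frame$pep1$resid, frame$pep1$peptide),
              peptide_backbone(move(frame$pep2$xyz), frame$pep2$resid, frame$pep2$peptide),
              box = NULL)
}

#' Per-replica dimer deviation summary
#'
#' Evaluates the three structure-quality criteria — backbone RMSD, absolute
#' crossing-angle deviation and signed contact-count deviation from the
#' reference — per frame over the analysis window, and returns their means
#' and standard deviations.
#'
#' @param frames list of [dimer_frame()] objects (one replica trajectory).
#' @param ref a [dimer_reference()].
#' @param last_fraction analysis window as the trailing fraction of the
#'   trajectory (default 0.5, e.g. the last 20 of 40 microseconds).
#' @param cutoff contact cutoff (nm), default 0.8.
#' @return list with `per_frame` (data frame `rmsd`, `dangle`, `dcontacts`)
#'   and scalar summaries `mean_rmsd`, `sd_rmsd`, `mean_dangle`,
#'   `sd_dangle`, `mean_dcontacts`, `sd_dcontacts`, `n_frames`.
#' @export
dimer_deviation_summary <- function(frames, ref, last_fraction = 0.5,
                                    cutoff = 0.8) {
  if (inherits(frames, "dimer_frame")) frames <- list(frames)
  .assert(length(frames) > 0, "no frames")
  .assert(last_fraction > 0 && last_fraction <= 1,
          "last_fraction must be in (0, 1]")
  n <- length(frames)
  keep <- frames[seq.int(n - floor(last_fraction * n) + 1, n)]
  .assert(length(keep) > 0, "empty analysis window")
  per <- data.frame(
    rmsd = vapply(keep, backbone_rmsd, numeric(1), ref = ref),
    dangle = vapply(keep, function(f)
      abs(crossing_angle(f, ref$range1, ref$range2) - ref$crossing), numeric(1)),
    dcontacts = vapply(keep, function(f)
      interpeptide_contacts(f, cutoff) - ref$n_contacts, numeric(1)))
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  list(per_frame = per,
       mean_rmsd = mean(per$rmsd), sd_rmsd = sd0(per$rmsd),
       mean_dangle = mean(per$dangle), sd_dangle = sd0(per$dangle),
       mean_dcontacts = mean(per$dcontacts), sd_dcontacts = sd0(per$dcontacts),
       n_frames = nrow(per))
}

#' Summarise dimer deviations across replicas
#'
#' @param replicas list of trajectories (each a list of [dimer_frame()]).
#' @inheritParams dimer_deviation_summary
#' @return data frame with one row per replica plus a final `mean` row
#'   averaging the per-replica means.
#' @export
replica_deviation_summary <- function(replicas, ref, last_fraction = 0.5,
                                      cutoff = 0.8) {
  .assert(length(replicas) > 0, "no replicas")
  rows <- lapply(seq_along(replicas), function(i) {
    s <- dimer_deviation_summary(replicas[[i]], ref, last_fraction, cutoff)
    data.frame(replica = as.character(i), mean_rmsd = s$mean_rmsd,
               sd_rmsd = s$sd_rmsd, mean_dangle = s$mean_dangle,
               sd_dangle = s$sd_dangle, mean_dcontacts = s$mean_dcontacts,
               sd_dcontacts = s$sd_dcontacts, n_frames = s$n_frames)
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(replica = "mean",
                         mean_rmsd = mean(out$mean_rmsd), sd_rmsd = NA_real_,
                         mean_dangle = mean(out$mean_dangle), sd_dangle = NA_real_,
                         mean_dcontacts = mean(out$mean_dcontacts),
                         sd_dcontacts = NA_real_, n_frames = sum(out$n_frames))
  rbind(out, mean_row)
}

#' Acceptable-region classifier for dimer deviations
#'
#' Pure threshold on the deviation summary: a replica is acceptable when
#' its mean RMSD and mean absolute crossing-angle deviation are both within
#' the stated limits (the rule-of-thumb region of 1 nm and 10 degrees).
#'
#' @param mean_rmsd mean backbone RMSD (nm).
#' @param mean_dangle mean absolute crossing-angle deviation (degrees).
#' @param rmsd_max RMSD limit (nm), default 1.
#' @param angle_max angle limit (degrees), default 10.
#' @return logical.
#' @export
acceptable_dimer <- function(mean_rmsd, mean_dangle, rmsd_max = 1, angle_max = 10) {
  mean_rmsd <= rmsd_max & mean_dangle <= angle_max
}
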