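## Oligomer-size analysis from peptide centre-of-mass trajectories:
## single-linkage clusters are the connected components of the graph
## joining peptides whose minimum-image COM distance is within the cutoff.

#' Mass-weighted peptide centres of mass with periodic unwrapping
#'
#' Each peptide's beads are unwrapped by the minimum image relative to its
#' first bead before the mass-weighted mean is taken, so molecules
#' straddling the periodic boundary get the physical COM; the result is
#' wrapped back into the primary box, making it independent of the anchor
#' bead whenever the peptide's diameter is below half the box.
#'
#' @param frame a [cg_frame()] (or list with `xyz` and `box`).
#' @param groups list of integer index vectors, one per peptide.
#' @param masses bead masses (amu): a single vector recycled across the
#'   frame, default 72 for every bead.
#' @return matrix n_peptides x 3 of COM coordinates (nm).
#' @export
compute_peptide_coms <- function(frame, groups, masses = NULL) {
  xyz <- frame$xyz; box <- frame$box
  masses <- masses %||% rep(72, nrow(xyz))
  masses <- rep_len(masses, nrow(xyz))
  .assert(all(masses > 0), "masses must be > 0")
  .assert(length(groups) > 0 && all(lengths(groups) > 0), "empty peptide group")
  out <- t(vapply(groups, function(idx) {
    x <- xyz[idx, , drop = FALSE]
    m <- masses[idx]
    anchor <- x[1, ]
    for (i in seq_len(nrow(x)))
      x[i, ] <- anchor + min_image(x[i, ] - anchor, box)
    com <- colSums(x * m) / sum(m)
    if (!is.null(box)) {
      com <- com %% box
      com <- ifelse(com > box - 1e-9, com - box, com)  # snap edge back to 0
    }
    com
  }, numeric(3)))
  unname(out)
}

#' Single-linkage clusters of peptide COMs
#'
#' Connected components of the contact graph with edges wherever the
#' minimum-image distance is within `cutoff`.  Labels are deterministic:
#' every member carries the lowest peptide index of its cluster.
#'
#' @param coms n x 3 matrix of COM coordinates (nm).
#' @param cutoff linkage cutoff (nm), default 2.5 — the distance at which
#'   peptide COM radial distribution functions decay to zero.
#' @param box orthorhombic box lengths (nm) or NULL.
#' @return integer label vector of length n.
#' @export
single_linkage_clusters <- function(coms, cutoff = 2.5, box = NULL) {
  coms <- rbind(coms)
  .assert(nrow(coms) >= 1, "need at least one COM")
  .assert(cutoff > 0, "cutoff must be > 0")
  .check_box(box)
  if (nrow(coms) == 1) return(1L)
  adj <- pair_distances(coms, coms, box) <= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  memb <- igraph::components(g)$membership
  relabel <- vapply(split(seq_along(memb), memb), min, integer(1))
  as.integer(relabel[as.character(memb)])
}

#' Construct a COM trajectory
#'
#' @param coms list of n x 3 COM matrices, one per frame (constant n).
#' @param box box lengths (nm): a single vector applied to all frames, or
#'   a list per frame.
#' @param times frame times (ns); defaults to `0:(T-1)`.
#' @return object of class `com_trajectory`.
#' @export
com_trajectory <- function(coms, box = NULL, times = NULL) {
  .assert(length(coms) > 0, "no frames")
  n <- nrow(rbind(coms[[1]]))
  .assert(all(vapply(coms, function(x) nrow(rbind(x)), integer(1)) == n),
          "peptide count varies across frames")
  if (!is.null(box) && !is.list(box)) box <- rep(list(box), length(coms))
  times <- times %||% (seq_along(coms) - 1)
  .assert(length(times) == length(coms) && all(diff(times) > 0),
          "times must be strictly increasing, one per frame")
  structure(list(coms = lapply(coms, rbind), box = box,
                 times = as.numeric(times), n_peptides = n),
            class = "com_trajectory")
}

#' Oligomer cluster-size statistics over a trajectory
#'
#' Per frame: single-linkage labels and the number-averaged cluster size
#' (total peptides divided by number of clusters; the weight-averaged mean
#' cluster size of each peptide's own cluster is also reported).  Over the
#' trailing histogram window, per-cluster sizes are pooled and normalized
#' to frequencies.
#'
#' @param traj a [com_trajectory()].
#' @param cutoff linkage cutoff (nm), default 2.5.
#' @param hist_last trailing fraction of frames pooled into the size
#'   histogram (default 0.25, e.g. the last 10 of 40 microseconds).
#' @return object of class `cluster_time_series`: list with `labels`
#'   (frames x peptides matrix), `mean_size` and `weight_mean_size` time
#'   series, `times`, and `histogram` (data frame `size`, `frequency`).
#' @export
cluster_size_stats <- function(traj, cutoff = 2.5, hist_last = 0.25) {
  .assert(inherits(traj, "com_trajectory"), "need a com_trajectory")
  .assert(hist_last > 0 && hist_last <= 1, "hist_last must be in (0, 1]")
  nfr <- length(traj$coms)
  labels <- matrix(NA_integer_, nfr, traj$n_peptides)
  mean_size <- weight_mean <- numeric(nfr)
  sizes_by_frame <- vector("list", nfr)
  for (t in seq_len(nfr)) {
    lab <- single_linkage_clusters(traj$coms[[t]], cutoff,
                                   if (is.null(traj$box)) NULL else traj$box[[t]])
    labels[t, ] <- lab
    sz <- as.numeric(table(lab))
    sizes_by_frame[[t]] <- sz
    mean_size[t] <- traj$n_peptides / length(sz)
    weight_mean[t] <- sum(sz^2) / traj$n_peptides
  }
  first <- nfr - floor(hist_last * nfr) + 1
  .assert(first <= nfr, "empty histogram window")
  pooled <- unlist(sizes_by_frame[first:nfr])
  tab <- table(factor(pooled, levels = seq_len(traj$n_peptides)))
  hist <- data.frame(size = as.integer(names(tab)),
                     frequency = as.numeric(tab) / sum(tab))
  structure(list(labels = labels, mean_size = mean_size,
                 weight_mean_size = weight_mean, times = traj$times,
                 histogram = hist, cutoff = cutoff,
                 window_frames = first:nfr),
            class = "cluster_time_series")
}

#' @export
print.cluster_time_series <- function(x, ...) {
  cat(sprintf("cluster_time_series: %d frames, %d peptides, cutoff %g nm\n",
              nrow(x$labels), ncol(x$labels), x$cutoff))
  cat(sprintf("  mean oligomer size: %.2f (first frame) -> %.2f (last frame)\n",
              x$mean_size[1], x$mean_size[length(x$mean_size)]))
  invisible(x)
}
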