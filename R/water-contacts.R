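## Water-contact residue classification for the "W" scaling strategy:
## a residue is rescaled when, summed over the retained frames, its beads
## have strictly more contacts with water beads than with lipid beads
## within the contact cutoff (minimum-image distances).

#' Classify water-contacting residues
#'
#' For each protein residue, counts bead-bead contacts (pairs within
#' `cutoff` under the minimum-image convention) against water beads and
#' against lipid beads, summed over the frames retained after the
#' equilibration skip.  Residues with strictly more water than lipid
#' contacts are classified as water-contacting; ties are not classified.
#'
#' @param frames a [cg_frame()] or list of them, containing protein, water
#'   and lipid beads.
#' @param cutoff contact cutoff in nm (default 0.6).
#' @param skip equilibration portion to discard: a fraction in `[0, 1)`
#'   (default 0.05, i.e. the leading 5 percent of frames) or an integer
#'   number of frames.
#' @return data frame with columns `peptide` and `resid` of the classified
#'   residues; the full per-residue contact counts are in attribute
#'   `"counts"` (columns `peptide`, `resid`, `n_water`, `n_lipid`,
#'   `water_contacting`).
#' @export
classify_water_contacting_residues <- function(frames, cutoff = 0.6, skip = 0.05) {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  .assert(length(frames) > 0 && all(vapply(frames, inherits, logical(1), "cg_frame")),
          "frames must be cg_frame objects")
  .assert(is.numeric(cutoff) && cutoff > 0, "cutoff must be > 0")
  nskip <- if (skip < 1) floor(skip * length(frames)) else as.integer(skip)
  kept <- frames[seq_along(frames) > nskip]
  .assert(length(kept) > 0, "no frames left after equilibration skip")

  tally <- list()
  for (fr in kept) {
    ip <- fr$category == "protein"
    iw <- fr$category == "water"
    il <- fr$category == "lipid"
    .assert(any(ip), "frame has no protein beads")
    .assert(any(iw) && any(il),
            "classification undefined: frame lacks water or lipid beads")
    dw <- pair_distances(fr$xyz[ip, , drop = FALSE],
                         fr$xyz[iw, , drop = FALSE], fr$box) <= cutoff
    dl <- pair_distances(fr$xyz[ip, , drop = FALSE],
                         fr$xyz[il, , drop = FALSE], fr$box) <= cutoff
    key <- paste(fr$peptide[ip], fr$resid[ip])
    nw <- rowSums(dw); nl <- rowSums(dl)
    for (k in unique(key)) {
      row <- tally[[k]] %||% c(0, 0)
      tally[[k]] <- row + c(sum(nw[key == k]), sum(nl[key == k]))
    }
  }
  ids <- do.call(rbind, strsplit(names(tally), " "))
  counts <- data.frame(peptide = as.integer(ids[, 1]),
                       resid = as.integer(ids[, 2]),
                       n_water = vapply(tally, `[`, numeric(1), 1),
                       n_lipid = vapply(tally, `[`, numeric(1), 2))
  counts <- counts[order(counts$peptide, counts$resid), ]
  counts$water_contacting <- counts$n_water > counts$n_lipid  # strict
  rownames(counts) <- NULL
  out <- counts[counts$water_contacting, c("peptide", "resid")]
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}
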