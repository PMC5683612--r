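## Rigid-body geometry primitives: Kabsch superposition and principal-axis
## extraction by SVD.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `ref`.  The standard sign correction is applied when the raw SVD
#' solution would be a reflection, so the returned rotation always has
#' determinant +1.
#'
#' @param mobile,ref numeric n x 3 matrices (n >= 3), equal row counts.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fit
#'   is `mobile %*% t(rotation) + translation`), `rmsd` (nm, the minimized
#'   value) and `fitted` (the transformed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, ref) {
  mobile <- rbind(mobile); ref <- rbind(ref)
  .assert(nrow(mobile) == nrow(ref), "point counts differ (%d vs %d)",
          nrow(mobile), nrow(ref))
  .assert(nrow(mobile) >= 3, "need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  s <- svd(crossprod(A, B))          # A^T B = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- sweep(A %*% t(R), 2, cr, "+")
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)),
       rmsd = sqrt(mean(rowSums((fitted - ref)^2))), fitted = fitted)
}

#' Principal axis of a bead set
#'
#' Direction of largest spread of the centred coordinates — the first right
#' singular vector of the centred coordinate matrix, i.e. the principal
#' moment axis used for helix orientation.  The sign is fixed so the axis
#' points from the first towards the last bead of the selection.
#'
#' @param backbone a `peptide_backbone` or plain n x 3 coordinate matrix.
#' @param residue_range optional `c(first, last)` residue ids restricting
#'   the selection (requires a `peptide_backbone`).
#' @return unit 3-vector.
#' @export
principal_axis <- function(backbone, residue_range = NULL) {
  if (inherits(backbone, "peptide_backbone")) {
    xyz <- backbone$xyz
    if (!is.null(residue_range)) {
      sel <- backbone$resid >= residue_range[1] & backbone$resid <= residue_range[2]
      .assert(any(sel), "residue range [%d, %d] selects no beads",
              residue_range[1], residue_range[2])
      xyz <- xyz[sel, , drop = FALSE]
    }
  } else {
    xyz <- rbind(backbone)
  }
  .assert(nrow(xyz) >= 3, "need at least 3 beads for an axis")
  ctr <- sweep(xyz, 2, colMeans(xyz))
  .assert(max(abs(ctr)) > 1e-12, "beads are coincident; axis undefined")
  v <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  span <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(v * span) < 0) v <- -v
  v / sqrt(sum(v^2))
}
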