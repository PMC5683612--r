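## Protein-protein interaction scaling.  The well depth of every targeted
## protein-protein pair is moved toward the repulsive floor:
##
##   eps_scaled = eps_repulsive + (1 - alpha) * (eps_original - eps_repulsive)
##
## alpha = 0 leaves the table untouched, alpha = 1 collapses every targeted
## pair onto the floor (2 kJ/mol for the standard Martini ladder).  Targeted
## bead types are duplicated under a new name so that protein-lipid,
## protein-water and all other interactions keep their original parameters.

#' Scale a Lennard-Jones well depth toward the repulsive floor
#'
#' @param eps_original original well depth (kJ/mol); must be at least
#'   `eps_repulsive` (scaling must never increase attraction).
#' @param alpha scaling strength, between 0 (no change) and 1 (floor).
#' @param eps_repulsive repulsive floor (kJ/mol), default 2.0, the weakest
#'   interaction level of the standard ladder.
#' @return scaled well depth in `[eps_repulsive, eps_original]`.
#' @export
#' @examples
#' scale_epsilon(5.6, 0.9)  # 2.36
#' scale_epsilon(5.6, 1.0)  # 2.0, the floor
scale_epsilon <- function(eps_original, alpha, eps_repulsive = 2.0) {
  .assert(is.numeric(alpha) && all(alpha >= 0 & alpha <= 1),
          "alpha must lie in [0, 1]")
  .assert(is.numeric(eps_repulsive) && all(eps_repulsive > 0),
          "eps_repulsive must be > 0")
  .assert(all(eps_original >= eps_repulsive),
          "eps_original < eps_repulsive would increase attraction")
  eps_repulsive + (1 - alpha) * (eps_original - eps_repulsive)
}

## per-pair scaling used by the table rewriters: pairs already at or below
## the floor (e.g. small-bead pairs whose ladder sits 25% lower) are fixed
## points rather than errors.
.scale_pair_eps <- function(eps, alpha, eps_repulsive) {
  floor_ <- pmin(eps, eps_repulsive)
  floor_ + (1 - alpha) * (eps - floor_)
}

.scaled_name <- function(names, suffix) paste0(names, suffix)

## duplicate `types_to_scale`, scale the mutual pairs of the duplicates,
## copy every cross pair unchanged
.duplicate_and_scale <- function(table, types_to_scale, alpha,
                                 eps_repulsive = 2.0, suffix = "_s") {
  .assert(is.numeric(alpha) && length(alpha) == 1 && alpha >= 0 && alpha <= 1,
          "alpha must lie in [0, 1]")
  types_to_scale <- sort(unique(types_to_scale))
  unknown <- setdiff(types_to_scale, table$types$name)
  .assert(length(unknown) == 0, "unknown type name(s): %s",
          paste(unknown, collapse = ", "))
  .assert(length(missing_pairs(table)) == 0,
          "input table is incomplete; complete it before scaling")
  if (length(types_to_scale) == 0)
    return(list(table = table, mapping = character(),
                audit = data.frame(type_i = character(), type_j = character(),
                                   eps_original = numeric(),
                                   eps_scaled = numeric(), sigma = numeric())))
  newnames <- .scaled_name(types_to_scale, suffix)
  clash <- intersect(newnames, table$types$name)
  .assert(length(clash) == 0,
          "duplicated-type name(s) collide with existing types: %s",
          paste(clash, collapse = ", "))
  mapping <- stats::setNames(newnames, types_to_scale)

  dup <- table$types[match(types_to_scale, table$types$name), ]
  dup$name <- newnames
  types <- rbind(table$types, dup)

  old <- table$pairs
  new_rows <- list(old)
  ## new-new pairs: Eq-style scaling of the original pair value
  for (ai in seq_along(types_to_scale)) {
    for (bi in ai:length(types_to_scale)) {
      a <- types_to_scale[ai]; b <- types_to_scale[bi]
      pr <- get_pair(table, a, b)
      new_rows[[length(new_rows) + 1]] <- data.frame(
        i = mapping[[a]], j = mapping[[b]],
        eps = .scale_pair_eps(pr[["eps"]], alpha, eps_repulsive),
        sigma = pr[["sigma"]])
    }
  }
  ## new-old pairs (including new vs unscaled originals of the same bead):
  ## original cross values, untouched
  for (a in types_to_scale) {
    for (b in table$types$name) {
      pr <- get_pair(table, a, b)
      new_rows[[length(new_rows) + 1]] <- data.frame(
        i = mapping[[a]], j = b, eps = pr[["eps"]], sigma = pr[["sigma"]])
    }
  }
  out <- nonbond_table(types, do.call(rbind, new_rows), dialect = table$dialect)

  audit <- do.call(rbind, lapply(seq_along(types_to_scale), function(ai) {
    do.call(rbind, lapply(ai:length(types_to_scale), function(bi) {
      a <- types_to_scale[ai]; b <- types_to_scale[bi]
      pr <- get_pair(table, a, b)
      data.frame(type_i = mapping[[a]], type_j = mapping[[b]],
                 eps_original = pr[["eps"]],
                 eps_scaled = .scale_pair_eps(pr[["eps"]], alpha, eps_repulsive),
                 sigma = pr[["sigma"]])
    }))
  }))
  list(table = out, mapping = mapping, audit = audit)
}

.new_scaled_ff <- function(original, core, strategy, alpha, eps_repulsive,
                           residues = NULL) {
  structure(list(original = original, scaled = core$table,
                 mapping = core$mapping, audit = core$audit,
                 strategy = strategy, alpha = alpha,
                 eps_repulsive = eps_repulsive, residues = residues),
            class = "scaled_forcefield")
}

#' @export
print.scaled_forcefield <- function(x, ...) {
  cat(sprintf("scaled_forcefield: strategy %s, alpha = %g, floor = %g kJ/mol\n",
              x$strategy, x$alpha, x$eps_repulsive))
  cat(sprintf("  %d type(s) duplicated, %d pair(s) rescaled\n",
              length(x$mapping), nrow(x$audit)))
  invisible(x)
}

#' Uniform ("U") scaling over all protein bead types
#'
#' Every bead type used by protein beads — including the polar and charged
#' types P4, Qa and Qd — is duplicated under a deterministic suffixed name;
#' well depths between two duplicated types follow [scale_epsilon()], while
#' every pair involving a non-duplicated type keeps its original value, so
#' lipid, water and ion interactions are untouched.
#'
#' @param table complete [nonbond_table()].
#' @param protein_types character vector of bead-type names used by the
#'   protein.
#' @param alpha scaling strength in `[0, 1]`.
#' @param eps_repulsive repulsive floor (kJ/mol).
#' @param suffix suffix for duplicated type names; a collision with an
#'   existing name is an error, never a silent rename.
#' @return a `scaled_forcefield`: the original and emitted tables, the
#'   original-to-scaled name mapping, and an audit table of rescaled pairs
#'   (`type_i`, `type_j`, `eps_original`, `eps_scaled`, `sigma`).
#' @export
apply_uniform_scaling <- function(table, protein_types, alpha,
                                  eps_repulsive = 2.0, suffix = "_s") {
  .assert(!(alpha > 0 && length(protein_types) == 0),
          "alpha > 0 with an empty protein type set")
  core <- .duplicate_and_scale(table, protein_types, alpha, eps_repulsive, suffix)
  .new_scaled_ff(table, core, "U", alpha, eps_repulsive)
}

#' Water-contact-restricted ("W") scaling
#'
#' Only beads belonging to residues classified as water-contacting (see
#' [classify_water_contacting_residues()]) are assigned duplicated types;
#' mutual interactions among the duplicates are scaled as in the uniform
#' strategy while interactions between scaled and unscaled protein beads
#' stay at their standard values.
#'
#' @param table complete [nonbond_table()].
#' @param classified_residues data frame with columns `peptide` and `resid`
#'   naming the residues to rescale (typically the output of
#'   [classify_water_contacting_residues()]).
#' @param residue_types data frame mapping residues to bead types, columns
#'   `peptide`, `resid`, `type` (one row per protein bead).
#' @inheritParams apply_uniform_scaling
#' @return a `scaled_forcefield`; `$residues` holds the classified residues
#'   with the bead types that were duplicated for them.
#' @export
apply_water_scaling <- function(table, classified_residues, residue_types,
                                alpha, eps_repulsive = 2.0, suffix = "_s") {
  .assert(is.data.frame(classified_residues) &&
            all(c("peptide", "resid") %in% names(classified_residues)),
          "classified_residues needs columns peptide, resid")
  .assert(is.data.frame(residue_types) &&
            all(c("peptide", "resid", "type") %in% names(residue_types)),
          "residue_types needs columns peptide, resid, type")
  key <- function(d) paste(d$peptide, d$resid)
  hit <- residue_types[key(residue_types) %in% key(classified_residues), ]
  .assert(nrow(classified_residues) == 0 || nrow(hit) > 0,
          "classified residues not found in residue_types")
  .assert(!(alpha > 0 && nrow(classified_residues) > 0 && nrow(hit) == 0),
          "alpha > 0 with an empty bead selection")
  core <- .duplicate_and_scale(table, unique(hit$type), alpha, eps_repulsive, suffix)
  .new_scaled_ff(table, core, "W", alpha, eps_repulsive, residues = hit)
}

#' Audit the difference between an emitted and its original table
#'
#' @param ff a `scaled_forcefield`.
#' @return data frame of all pairs whose eps differs between the emitted
#'   and original tables (duplicated pairs compared against the pair of
#'   their source types).
#' @export
scaling_diff <- function(ff) {
  orig <- ff$original; new <- ff$scaled
  back <- function(nm) {
    hit <- match(nm, ff$mapping)
    ifelse(is.na(hit), nm, names(ff$mapping)[hit])
  }
  p <- new$pairs
  p$eps_original <- mapply(function(a, b) get_pair(orig, back(a), back(b))[["eps"]],
                           p$i, p$j)
  p[abs(p$eps - p$eps_original) > 1e-12,
    c("i", "j", "eps_original", "eps", "sigma")]
}
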