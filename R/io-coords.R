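## Coordinate frames (GRO / PDB).  Coordinates are stored in nm everywhere;
## PDB Angstrom values are divided by 10 on read.  Orthorhombic boxes only.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

## default residue-name -> bead-category mapping for Martini-style systems
.default_category <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- rep("lipid", length(resname))
  out[resname %in% c("W", "WF", "PW", "SOL", "HOH")] <- "water"
  out[resname %in% c("ION", "NA", "CL", "NA+", "CL-", "K", "K+", "CA", "CA2+")] <- "ion"
  out[resname %in% .AA3] <- "protein"
  out
}

#' Construct a coordinate frame
#'
#' @param xyz numeric n x 3 matrix of bead coordinates (nm).
#' @param category character vector, one of `"protein"`, `"lipid"`,
#'   `"water"`, `"ion"` per bead.
#' @param resid integer residue ids (1-based); required for protein beads.
#' @param peptide integer peptide/chain id per bead (NA for non-protein).
#' @param box orthorhombic box lengths (nm, length 3), or NULL.
#' @return object of class `cg_frame`.
#' @export
cg_frame <- function(xyz, category, resid = NA_integer_, peptide = NA_integer_,
                     box = NULL) {
  xyz <- rbind(xyz)
  .assert(ncol(xyz) == 3 && all(is.finite(xyz)), "xyz must be finite n x 3 (nm)")
  n <- nrow(xyz)
  category <- rep_len(category, n)
  .assert(all(category %in% c("protein", "lipid", "water", "ion")),
          "unknown bead category")
  .check_box(box)
  structure(list(xyz = unname(xyz), category = category,
                 resid = rep_len(as.integer(resid), n),
                 peptide = rep_len(as.integer(peptide), n), box = box),
            class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("cg_frame: %d beads (%s)%s\n", nrow(x$xyz),
              paste(sprintf("%d %s", table(x$category),
                            names(table(x$category))), collapse = ", "),
              if (is.null(x$box)) "" else
                sprintf(", box %s nm", paste(format(x$box), collapse = " x "))))
  invisible(x)
}

.read_gro <- function(lines) {
  .assert(length(lines) >= 3, "truncated GRO: need title, count and box lines")
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  .assert(!is.na(natoms), "line 2: atom count is not an integer")
  .assert(length(lines) >= natoms + 3, "truncated GRO: %d atom lines expected", natoms)
  rec <- lines[3:(natoms + 2)]
  bad <- which(nchar(rec) < 44)
  .assert(length(bad) == 0, "line %d: truncated GRO record", bad[1] + 2)
  resid <- suppressWarnings(as.integer(substr(rec, 1, 5)))
  resname <- trimws(substr(rec, 6, 10))
  x <- suppressWarnings(as.numeric(substr(rec, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(rec, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(rec, 37, 44)))
  .assert(!anyNA(c(resid, x, y, z)), "non-numeric field in GRO atom record")
  boxtok <- suppressWarnings(
    as.numeric(strsplit(trimws(lines[natoms + 3]), "\\s+")[[1]]))
  .assert(length(boxtok) >= 3 && !anyNA(boxtok[1:3]), "missing or malformed GRO box line")
  .assert(length(boxtok) == 3 || all(abs(boxtok[-(1:3)]) < 1e-12),
          "triclinic boxes are not supported")
  list(xyz = cbind(x, y, z), resid = resid, resname = resname,
       chain = rep(NA_character_, natoms), box = boxtok[1:3])
}

.read_pdb <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  p <- bio3d::read.pdb(tf, verbose = FALSE)
  a <- p$atom
  .assert(nrow(a) > 0, "no ATOM/HETATM records found")
  box <- NULL
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) >= 1) {
    v <- suppressWarnings(as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                                       substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                                       substr(cl[1], 41, 47), substr(cl[1], 48, 54))))
    .assert(!anyNA(v[1:3]), "malformed CRYST1 record")
    .assert(all(abs(v[4:6] - 90) < 1e-6), "triclinic boxes are not supported")
    box <- v[1:3] / 10  # Angstrom -> nm
  }
  list(xyz = cbind(a$x, a$y, a$z) / 10, resid = a$resno, resname = a$resid,
       chain = a$chain, box = box)
}

## peptide ids: by chain where available, else by breaks in residue numbering
.assign_peptides <- function(resid, chain, is_protein) {
  pep <- rep(NA_integer_, length(resid))
  idx <- which(is_protein)
  if (length(idx) == 0) return(pep)
  if (!all(is.na(chain[idx]))) {
    pep[idx] <- as.integer(factor(chain[idx], levels = unique(chain[idx])))
  } else {
    r <- resid[idx]
    newpep <- c(TRUE, diff(r) < 0)
    pep[idx] <- cumsum(newpep)
  }
  pep
}

#' Read a coordinate frame from GRO or PDB text
#'
#' PDB coordinates (Angstrom) are converted to nm; the box is taken from the
#' GRO box line or the PDB CRYST1 record.  Bead categories are inferred from
#' residue names (water/ion names, the 20 amino acids, everything else
#' lipid) unless `category` is supplied.  Protein beads get peptide ids from
#' the chain id (PDB) or from restarts in residue numbering (GRO).
#'
#' @param text file path, single string, or character vector of lines.
#' @param format `"GRO"` or `"PDB"`.
#' @param category optional explicit per-bead category vector.
#' @param require_box error when no box is present (needed for any
#'   periodic-boundary-aware metric downstream).
#' @return a [cg_frame()].
#' @export
read_coordinates <- function(text, format = c("GRO", "PDB"), category = NULL,
                             require_box = TRUE) {
  format <- match.arg(format)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- .split_lines(text)
  raw <- if (format == "GRO") .read_gro(lines) else .read_pdb(lines)
  if (require_box)
    .assert(!is.null(raw$box), "no box found (%s); a box is required", format)
  if (is.null(category)) category <- .default_category(raw$resname)
  pep <- .assign_peptides(raw$resid, raw$chain, category == "protein")
  cg_frame(raw$xyz, category, resid = raw$resid, peptide = pep, box = raw$box)
}
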