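## Nonbonded parameter tables: GROMACS ITP dialect ([ atomtypes ],
## [ nonbond_params ], func type 1), sigma-epsilon or C6/C12 form.
## Internally everything is stored as sigma-epsilon with canonical
## (lexicographically ordered) unordered pairs, so symmetry holds by
## construction.

#' Construct a nonbonded interaction table
#'
#' A symmetric per-pair Lennard-Jones table keyed by bead-type name, the
#' in-memory form of a GROMACS `[ nonbond_params ]` section.  Pairs are
#' stored once with type names in lexicographic order; lookups are symmetric.
#'
#' @param types data frame with columns `name`, `mass` (amu), `charge` (e)
#'   and logical `small` (small/ring bead flag).  `mass`, `charge`, `small`
#'   are optional and default to 72, 0 and FALSE.
#' @param pairs data frame with columns `i`, `j` (type names), `eps`
#'   (kJ/mol) and `sigma` (nm).
#' @param dialect source dialect tag, `"sigma-eps"` or `"c6c12"`.
#' @return object of class `nonbond_table` with elements `types`, `pairs`
#'   and `dialect`.
#' @export
nonbond_table <- function(types, pairs = NULL, dialect = "sigma-eps") {
  if (is.character(types)) types <- data.frame(name = types)
  .assert(is.data.frame(types) && "name" %in% names(types), "types needs a 'name' column")
  .assert(!anyDuplicated(types$name), "duplicated type names")
  if (is.null(types$mass)) types$mass <- rep(72, nrow(types))
  if (is.null(types$charge)) types$charge <- rep(0, nrow(types))
  if (is.null(types$small)) types$small <- rep(FALSE, nrow(types))
  types <- types[order(types$name), c("name", "mass", "charge", "small")]
  if (is.null(pairs)) {
    pairs <- data.frame(i = character(), j = character(),
                        eps = numeric(), sigma = numeric())
  }
  .assert(all(c("i", "j", "eps", "sigma") %in% names(pairs)),
          "pairs needs columns i, j, eps, sigma")
  unknown <- setdiff(unique(c(pairs$i, pairs$j)), types$name)
  .assert(length(unknown) == 0, "pair entries reference undeclared types: %s",
          paste(unknown, collapse = ", "))
  .assert(all(pairs$eps >= 0), "epsilon must be >= 0")
  .assert(all(pairs$sigma > 0), "sigma must be > 0")
  ## canonicalize: i <= j lexicographically
  flip <- pairs$i > pairs$j
  tmp <- pairs$i[flip]; pairs$i[flip] <- pairs$j[flip]; pairs$j[flip] <- tmp
  key <- paste(pairs$i, pairs$j)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    agree <- vapply(unique(dup), function(k) {
      sub <- pairs[key == k, ]
      max(abs(diff(sub$eps)), abs(diff(sub$sigma))) < 1e-9
    }, logical(1))
    .assert(all(agree), "conflicting duplicate pair(s): %s",
            paste(unique(dup)[!agree], collapse = "; "))
    pairs <- pairs[!duplicated(key), ]
  }
  pairs <- pairs[order(pairs$i, pairs$j), c("i", "j", "eps", "sigma")]
  rownames(types) <- rownames(pairs) <- NULL
  structure(list(types = types, pairs = pairs, dialect = dialect),
            class = "nonbond_table")
}

#' @export
print.nonbond_table <- function(x, ...) {
  cat(sprintf("nonbond_table: %d types, %d/%d pairs (%s dialect)\n",
              nrow(x$types), nrow(x$pairs),
              nrow(x$types) * (nrow(x$types) + 1) / 2, x$dialect))
  invisible(x)
}

## pairs of declared types absent from the table (character vector "A B")
missing_pairs <- function(table) {
  nm <- sort(table$types$name)
  if (length(nm) == 0) return(character())
  all_pairs <- outer(nm, nm, paste)[upper.tri(diag(length(nm)), diag = TRUE)]
  setdiff(all_pairs, paste(table$pairs$i, table$pairs$j))
}

#' Look up a symmetric pair entry
#'
#' @param table a [nonbond_table()].
#' @param a,b type names (order irrelevant).
#' @return named numeric vector `c(eps = , sigma = )`.
#' @export
get_pair <- function(table, a, b) {
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  hit <- which(table$pairs$i == a & table$pairs$j == b)
  .assert(length(hit) == 1, "no entry for pair (%s, %s)", a, b)
  c(eps = table$pairs$eps[hit], sigma = table$pairs$sigma[hit])
}

#' Lennard-Jones C6/C12 to sigma-epsilon conversion
#'
#' `eps = C6^2 / (4 C12)`, `sigma = (C12/C6)^(1/6)`; the exact inverse of
#' [sigma_eps_to_c6c12()].
#'
#' @param c6 attractive coefficient (kJ mol^-1 nm^6).
#' @param c12 repulsive coefficient (kJ mol^-1 nm^12).
#' @return list with `eps` (kJ/mol) and `sigma` (nm).
#' @export
#' @examples
#' c6c12_to_sigma_eps(0.241454, 0.00260268) # eps ~5.6, sigma ~0.47
c6c12_to_sigma_eps <- function(c6, c12) {
  .assert(all(c6 > 0) && all(c12 > 0),
          "C6/C12 form requires positive coefficients for conversion")
  list(eps = c6^2 / (4 * c12), sigma = (c12 / c6)^(1 / 6))
}

#' @rdname c6c12_to_sigma_eps
#' @param eps well depth (kJ/mol).
#' @param sigma interaction distance (nm).
#' @export
sigma_eps_to_c6c12 <- function(eps, sigma) {
  .assert(all(eps >= 0) && all(sigma > 0), "need eps >= 0, sigma > 0")
  list(c6 = 4 * eps * sigma^6, c12 = 4 * eps * sigma^12)
}

.split_lines <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

## strip ';' comments and trailing whitespace; returns "" for pure comments
.strip_comment <- function(line) sub("\\s+$", "", sub(";.*$", "", line))

#' Read a GROMACS-dialect nonbonded parameter file
#'
#' Parses `[ atomtypes ]` and `[ nonbond_params ]` sections (func type 1).
#' Pair lines carry either `sigma epsilon` or `C6 C12`; C6/C12 entries are
#' converted to sigma-epsilon on read.  Comment lines start with `;`.
#'
#' @param text file path, single string, or character vector of lines.
#' @param form `"sigma-eps"`, `"c6c12"`, or `"auto"` (guess from the data:
#'   C12 coefficients are orders of magnitude below C6 while epsilon
#'   exceeds sigma for Martini-scale parameters).
#' @return a [nonbond_table()]; any pairs of declared types without an
#'   entry are reported with a warning and left absent.
#' @export
read_nonbond_params <- function(text, form = c("auto", "sigma-eps", "c6c12")) {
  form <- match.arg(form)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- .split_lines(text)
  section <- ""
  at <- list(); nb <- list()
  for (ln in seq_along(lines)) {
    raw <- .strip_comment(lines[ln])
    if (!nzchar(trimws(raw))) next
    sec <- regmatches(raw, regexec("^\\s*\\[\\s*([A-Za-z_]+)\\s*\\]\\s*$", raw))[[1]]
    if (length(sec) == 2) { section <- tolower(sec[2]); next }
    tok <- strsplit(trimws(raw), "\\s+")[[1]]
    if (section == "atomtypes") {
      .assert(length(tok) >= 4, "line %d: malformed [ atomtypes ] entry", ln)
      mass <- suppressWarnings(as.numeric(tok[2]))
      chg <- suppressWarnings(as.numeric(tok[3]))
      .assert(!is.na(mass) && !is.na(chg),
              "line %d: non-numeric mass/charge in [ atomtypes ]", ln)
      at[[length(at) + 1]] <- data.frame(name = tok[1], mass = mass, charge = chg)
    } else if (section == "nonbond_params") {
      .assert(length(tok) >= 5, "line %d: malformed [ nonbond_params ] entry", ln)
      .assert(tok[3] == "1", "line %d: only func type 1 is supported", ln)
      v <- suppressWarnings(as.numeric(tok[4]))
      w <- suppressWarnings(as.numeric(tok[5]))
      .assert(!is.na(v) && !is.na(w), "line %d: non-numeric pair parameters", ln)
      nb[[length(nb) + 1]] <- data.frame(i = tok[1], j = tok[2], V = v, W = w, line = ln)
    } else if (section != "") {
      next  # foreign sections are skipped
    } else {
      stop(sprintf("line %d: data outside any recognised section", ln), call. = FALSE)
    }
  }
  nbd <- if (length(nb)) do.call(rbind, nb) else
    data.frame(i = character(), j = character(), V = numeric(), W = numeric())
  if (form == "auto") {
    form <- if (nrow(nbd) > 0 && stats::median(nbd$V) > stats::median(nbd$W))
      "c6c12" else "sigma-eps"
  }
  if (form == "c6c12" && nrow(nbd) > 0) {
    conv <- c6c12_to_sigma_eps(nbd$V, nbd$W)
    pairs <- data.frame(i = nbd$i, j = nbd$j, eps = conv$eps, sigma = conv$sigma)
  } else {
    pairs <- data.frame(i = nbd$i, j = nbd$j, eps = nbd$W, sigma = nbd$V)
  }
  types <- if (length(at)) do.call(rbind, at) else
    data.frame(name = unique(c(pairs$i, pairs$j)))
  if (is.null(types$mass)) types$mass <- rep(72, nrow(types))
  types$small <- types$mass <= 45  # Martini small/ring beads are 45 amu
  tab <- nonbond_table(types, pairs, dialect = form)
  miss <- missing_pairs(tab)
  if (length(miss))
    warning(sprintf("%d declared pair(s) without parameters: %s",
                    length(miss), paste(miss, collapse = "; ")), call. = FALSE)
  tab
}

#' Write a nonbonded parameter table as ITP-dialect text
#'
#' Pairs are emitted in lexicographic order with 6 significant digits (the
#' documented round-trip precision); the output re-parses to an equal table.
#'
#' @param table a complete [nonbond_table()].
#' @param form output dialect, `"sigma-eps"` (default) or `"c6c12"`.
#' @param file optional path; if given the text is also written there.
#' @return character vector of lines, invisibly when `file` is given.
#' @export
write_nonbond_params <- function(table, form = c("sigma-eps", "c6c12"), file = NULL) {
  form <- match.arg(form)
  miss <- missing_pairs(table)
  .assert(length(miss) == 0, "incomplete pair table; missing: %s",
          paste(miss, collapse = "; "))
  out <- c("[ atomtypes ]", "; name  mass  charge  ptype")
  if (nrow(table$types) > 0)
    out <- c(out, sprintf("%-6s %8s %8s  A", table$types$name,
                          fmt6(table$types$mass), fmt6(table$types$charge)))
  out <- c(out, "", "[ nonbond_params ]")
  p <- table$pairs
  if (form == "c6c12") {
    cc <- sigma_eps_to_c6c12(p$eps, p$sigma)
    out <- c(out, "; i  j  func  C6  C12",
             if (nrow(p)) sprintf("%-6s %-6s 1 %12s %12s", p$i, p$j,
                                  fmt6(cc$c6), fmt6(cc$c12)))
  } else {
    out <- c(out, "; i  j  func  sigma  epsilon",
             if (nrow(p)) sprintf("%-6s %-6s 1 %10s %10s", p$i, p$j,
                                  fmt6(p$sigma), fmt6(p$eps)))
  }
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Test two nonbonded tables for equality
#'
#' @param a,b tables to compare.
#' @param tol absolute tolerance on eps/sigma.
#' @return TRUE/FALSE.
#' @export
nonbond_equal <- function(a, b, tol = 1e-9) {
  if (!identical(a$types$name, b$types$name)) return(FALSE)
  if (nrow(a$pairs) != nrow(b$pairs)) return(FALSE)
  if (!identical(paste(a$pairs$i, a$pairs$j), paste(b$pairs$i, b$pairs$j)))
    return(FALSE)
  all(abs(a$pairs$eps - b$pairs$eps) <= tol) &&
    all(abs(a$pairs$sigma - b$pairs$sigma) <= tol)
}
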