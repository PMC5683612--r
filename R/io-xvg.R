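## XVG-like two-column (or wider) time-series text, as written by the
## GROMACS analysis tools: '@' and '#' lines are headers, data rows are
## whitespace-separated floats.

#' Read an XVG-like time series
#'
#' @param text file path, single string, or character vector of lines.
#' @param col_names optional column names; defaults to `time`, `v1`, ...
#' @return data frame of numeric columns, first column strictly increasing
#'   time; header lines are kept in attribute `"header"`.
#' @export
read_xvg <- function(text, col_names = NULL) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- .split_lines(text)
  is_hdr <- grepl("^\\s*[@#]", lines) | !nzchar(trimws(lines))
  data <- lines[!is_hdr]
  .assert(length(data) > 0, "no data rows")
  toks <- strsplit(trimws(data), "\\s+")
  ncol <- length(toks[[1]])
  .assert(all(lengths(toks) == ncol), "line %d: ragged row (expected %d fields)",
          which(lengths(toks) != ncol)[1], ncol)
  vals <- suppressWarnings(vapply(toks, as.numeric, numeric(ncol)))
  vals <- if (ncol == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop(sprintf("data line %d: non-numeric token", bad), call. = FALSE)
  }
  if (is.null(col_names)) col_names <- c("time", paste0("v", seq_len(ncol - 1)))
  df <- as.data.frame(vals)
  names(df) <- col_names[seq_len(ncol)]
  attr(df, "header") <- lines[grepl("^\\s*[@#]", lines)]
  df
}

#' Write an XVG-like time series
#'
#' @param df data frame of numeric columns.
#' @param file optional output path.
#' @param header optional header lines (prefixed with `@` if not already).
#' @return character vector of lines, invisibly when `file` is given.
#' @export
write_xvg <- function(df, file = NULL, header = NULL) {
  .assert(is.data.frame(df) && nrow(df) > 0, "need a non-empty data frame")
  if (!is.null(header))
    header <- ifelse(grepl("^[@#]", header), header, paste("@", header))
  body <- do.call(sprintf, c(list(paste(rep("%.10g", ncol(df)), collapse = "  ")),
                             unname(as.list(df))))
  out <- c(header, body)
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}
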