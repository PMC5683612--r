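## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, ...) {
  if (!ok) stop(sprintf(...), call. = FALSE)
}

## minimum-image displacement for an orthorhombic box; x may be a matrix
## (rows = vectors) or a single 3-vector.  box = NULL means no periodicity.
min_image <- function(dx, box = NULL) {
  if (is.null(box)) return(dx)
  if (is.matrix(dx)) {
    for (d in seq_len(ncol(dx))) dx[, d] <- dx[, d] - box[d] * round(dx[, d] / box[d])
    dx
  } else {
    dx - box * round(dx / box)
  }
}

## all pairwise minimum-image distances between rows of a and rows of b
pair_distances <- function(a, b, box = NULL) {
  a <- rbind(a); b <- rbind(b)
  n <- nrow(a); m <- nrow(b)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dx <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) dx <- dx - box[k] * round(dx / box[k])
    d2 <- d2 + dx * dx
  }
  sqrt(d2)
}

.check_box <- function(box) {
  if (is.null(box)) return(invisible(NULL))
  .assert(is.numeric(box) && length(box) == 3 && all(is.finite(box)) && all(box > 0),
          "box must be three positive lengths (nm), got: %s",
          paste(format(box), collapse = " "))
  invisible(box)
}

## deterministic 6-significant-digit formatting used by all text writers
fmt6 <- function(x) formatC(x, digits = 6, format = "g", width = 1)
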