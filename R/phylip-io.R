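#' Read a PHYLIP distance matrix
#'
#' Reads the two distance-matrix dialects used by large-scale
#' neighbor-joining pipelines: the relaxed lower-triangular dialect (taxon
#' count line, then one line per taxon holding its name followed by the
#' distances to all previously listed taxa; names are whitespace-delimited
#' and not limited to 10 characters) and the full square dialect. Gzip
#' input is detected from the leading magic bytes (`0x1f 0x8b`), not the
#' file name.
#'
#' @param file path to a plain or gzip-compressed matrix file.
#' @param dialect `"relaxed_lower"` (default) or `"full"`. Full matrices
#'   are checked for symmetry to a tolerance of `1e-6 * max(|D|)` and the
#'   lower triangle is retained.
#' @return an [dist_matrix()] object in double precision.
#' @examples
#' f <- tempfile()
#' writeLines(c("3", "A", "B 2.0", "C 3.0 4.0"), f)
#' m <- read_phylip(f)
#' as.matrix(m)
#' @export
read_phylip <- function(file, dialect = c("relaxed_lower", "full")) {
  dialect <- match.arg(dialect)
  lines <- read_maybe_gzip(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input: ", file)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("line 1: expected a positive taxon count, got '", lines[1L], "'")
  body <- lines[-1L]
  if (length(body) != n)
    stop("expected ", n, " taxon lines, found ", length(body))

  labels <- character(n)
  tri <- numeric(n * (n - 1L) / 2L)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "[ \t]+")[[1L]]
    labels[i] <- tok[1L]
    vals <- suppressWarnings(as.numeric(tok[-1L]))
    if (anyNA(vals))
      stop("line ", i + 1L, " ('", labels[i], "'): non-numeric distance")
    want <- if (dialect == "relaxed_lower") i - 1L else n
    if (length(vals) != want)
      stop("line ", i + 1L, " ('", labels[i], "'): expected ", want,
           " distances, found ", length(vals))
    if (dialect == "relaxed_lower") {
      if (i > 1L) tri[tri_idx(i, 1L) + seq_len(i - 1L) - 1L] <- vals
    } else {
      if (i == 1L) full <- matrix(NA_real_, n, n)
      full[i, ] <- vals
    }
  }

  if (dialect == "full") {
    tol <- 1e-6 * max(abs(full))
    if (max(abs(full - t(full))) > tol)
      stop("full matrix is asymmetric beyond tolerance ",
           format(tol, digits = 3))
    tri <- full[lower_tri_index_pairs(n)]
  }
  if (any(tri < 0))
    stop("negative distance in input (cell ", which(tri < 0)[1L], ")")
  new_nj_dist(tri, labels)
}

read_maybe_gzip <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  magic <- readBin(file, what = "raw", n = 2L)
  con <- if (length(magic) == 2L && magic[1L] == as.raw(0x1f) &&
             magic[2L] == as.raw(0x8b)) gzfile(file, "rt") else file(file, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Write a PHYLIP distance matrix
#'
#' Serializes an `nj_dist` object in either dialect. Distances are always
#' written dequantized (cell times scale) with 17 significant digits, so a
#' double-precision write/read round trip is exact.
#'
#' @inheritParams read_phylip
#' @param m an `nj_dist` object.
#' @param gzip compress the output with gzip.
#' @return `file`, invisibly.
#' @export
write_phylip <- function(m, file, dialect = c("relaxed_lower", "full"),
                         gzip = FALSE) {
  stopifnot(inherits(m, "nj_dist"))
  dialect <- match.arg(dialect)
  n <- m$n
  fmt <- function(v) sprintf("%.17g", v)
  lines <- character(n + 1L)
  lines[1L] <- as.character(n)
  if (dialect == "relaxed_lower") {
    d <- distances(m)
    for (i in seq_len(n)) {
      row <- if (i > 1L) d[tri_idx(i, 1L) + seq_len(i - 1L) - 1L] else numeric(0)
      lines[i + 1L] <- paste(c(m$labels[i], fmt(row)), collapse = " ")
    }
  } else {
    full <- as.matrix(m)
    for (i in seq_len(n))
      lines[i + 1L] <- paste(c(m$labels[i], fmt(full[i, ])), collapse = " ")
  }
  con <- if (gzip) gzfile(file, "wt") else file(file, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}

#' Quantize a distance matrix to 1- or 2-byte cells
#'
#' Maps floating distances onto `L + 1` evenly spaced levels
#' (`L = 255` for `uint8`, `65535` for `uint16`): the scale is
#' `max(D) / L` and each cell becomes `round_half_up(d / scale)`, so the
#' dequantized value differs from the original by at most `scale / 2`.
#' Byte precision caps the matrix at 256 distinct distance values; row
#' sums and join criteria are nevertheless computed in double precision
#' downstream, so the join search still discriminates among
#' `(2n - 2) * 256` possible criterion values while branch lengths inherit
#' the coarse grid.
#'
#' @param m an `nj_dist` object in a floating precision mode.
#' @param precision `"uint16"` or `"uint8"`.
#' @return a quantized `nj_dist`; true distances are `cell * scale`.
#' @examples
#' m <- dist_matrix(c(2, 5, 10))
#' q <- quantize(m, "uint8")
#' q$x       # 51 128 255
#' q$scale   # 10/255
#' @export
quantize <- function(m, precision = c("uint16", "uint8")) {
  stopifnot(inherits(m, "nj_dist"))
  precision <- match.arg(precision)
  if (!m$precision %in% c("double", "float"))
    stop("matrix is already quantized (", m$precision, ")")
  top <- max(m$x)
  if (top <= 0) stop("cannot quantize an all-zero matrix: scale undefined")
  L <- if (precision == "uint8") 255 else 65535
  scale <- top / L
  cells <- round_half_up(m$x / scale)
  cells <- pmin(cells, L)  # guard against 0.5-ulp overshoot at the top level
  new_nj_dist(cells, m$labels, precision = precision, scale = scale)
}

round_half_up <- function(v) floor(v + 0.5)
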