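#' Lower-triangular distance matrix
#'
#' `dist_matrix()` builds the package's distance-matrix container: a
#' row-major lower triangle (row `i` holds the distances to the `i - 1`
#' taxa listed before it) with taxon labels, a storage precision mode and,
#' for the integer modes, a quantization scale. The triangle is the only
#' stored copy of the distances, mirroring the memory layout used by
#' large-scale neighbor-joining tools; self-distances are implicitly zero
#' and never stored.
#'
#' @param x a symmetric numeric matrix, a [stats::dist] object, or a
#'   numeric vector already in row-major lower-triangular order.
#' @param labels taxon names; defaults to dimnames of `x` or `t1..tn`.
#' @param precision storage mode. `"double"` and `"float"` store the
#'   values as given; `"uint16"`/`"uint8"` mark `x` as quantized integer
#'   cells whose true distance is `cell * scale` (see [quantize()]).
#' @param scale positive quantization factor; must be 1 for floating modes.
#' @return an object of class `"nj_dist"` with fields `labels`, `x`
#'   (the triangle, length `n(n-1)/2`), `n`, `precision` and `scale`.
#' @examples
#' m <- dist_matrix(rbind(c(0, 2, 3), c(2, 0, 4), c(3, 4, 0)),
#'                  labels = c("A", "B", "C"))
#' as.matrix(m)
#' @seealso [read_phylip()], [quantize()], [distances()]
#' @export
dist_matrix <- function(x, labels = NULL,
                        precision = c("double", "float", "uint16", "uint8"),
                        scale = 1) {
  precision <- match.arg(precision)
  if (inherits(x, "dist")) {
    labels <- labels %||% attr(x, "Labels")
    x <- as.matrix(x)
  }
  if (is.matrix(x)) {
    n <- nrow(x)
    if (ncol(x) != n) stop("distance matrix must be square")
    labels <- labels %||% rownames(x) %||% paste0("t", seq_len(n))
    tri <- x[lower_tri_index_pairs(n)]
  } else {
    len <- length(x)
    n <- (1 + sqrt(1 + 8 * len)) / 2
    if (abs(n - round(n)) > 1e-9)
      stop("triangle length ", len, " is not n(n-1)/2 for any integer n")
    n <- as.integer(round(n))
    labels <- labels %||% paste0("t", seq_len(n))
    tri <- as.numeric(x)
  }
  new_nj_dist(tri, labels, precision, scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## row-major lower-triangle cell (i,k), k < i, 1-based
tri_idx <- function(i, k) ((i - 1L) * (i - 2L)) %/% 2L + k

## (row, col) index matrix addressing a full square matrix in the
## row-major order of the stored triangle
lower_tri_index_pairs <- function(n) {
  if (n < 2L) return(cbind(integer(0), integer(0)))
  i <- rep.int(2:n, 1:(n - 1L))
  k <- sequence(1:(n - 1L))
  cbind(i, k)
}

new_nj_dist <- function(tri, labels, precision = "double", scale = 1) {
  m <- structure(
    list(labels = as.character(labels), x = as.numeric(tri),
         n = length(labels), precision = precision, scale = as.numeric(scale)),
    class = "nj_dist")
  validate_nj_dist(m)
  m
}

validate_nj_dist <- function(m) {
  n <- m$n
  if (n < 1L) stop("a distance matrix needs at least one taxon")
  if (anyDuplicated(m$labels)) stop("taxon labels must be unique")
  if (length(m$x) != n * (n - 1L) / 2L)
    stop("triangle holds ", length(m$x), " cells; expected n(n-1)/2 = ",
         n * (n - 1L) / 2L)
  if (anyNA(m$x)) stop("distances contain NA")
  if (any(m$x < 0)) stop("negative distance at cell ", which(m$x < 0)[1L])
  if (m$scale <= 0) stop("scale must be positive")
  if (m$precision %in% c("double", "float") && m$scale != 1)
    stop("scale must be 1 in floating precision modes")
  if (m$precision %in% c("uint8", "uint16")) {
    top <- if (m$precision == "uint8") 255 else 65535
    if (any(m$x != round(m$x)) || any(m$x > top))
      stop("quantized cells must be integers in [0, ", top, "]")
  }
  invisible(m)
}

#' True (dequantized) distances of a matrix
#'
#' Returns the stored triangle on the original distance scale: for the
#' integer precision modes each cell is multiplied by the quantization
#' scale, for floating modes the triangle is returned as is.
#'
#' @param m an `nj_dist` object.
#' @return numeric vector of length `n(n-1)/2` in row-major
#'   lower-triangular order.
#' @export
distances <- function(m) {
  stopifnot(inherits(m, "nj_dist"))
  if (m$precision %in% c("uint8", "uint16")) m$x * m$scale else m$x
}

#' @export
as.matrix.nj_dist <- function(x, ...) {
  n <- x$n
  full <- matrix(0, n, n, dimnames = list(x$labels, x$labels))
  idx <- lower_tri_index_pairs(n)
  d <- distances(x)
  full[idx] <- d
  full[idx[, c(2, 1), drop = FALSE]] <- d
  full
}

#' @export
as.dist.nj_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(as.matrix(m), diag = diag, upper = upper)
}

#' @export
print.nj_dist <- function(x, ...) {
  cat(sprintf("nj_dist: %d taxa, %s precision%s\n", x$n, x$precision,
              if (x$precision %in% c("uint8", "uint16"))
                sprintf(" (scale %.6g)", x$scale) else ""))
  d <- distances(x)
  if (length(d))
    cat(sprintf("  %d stored cells, range [%.6g, %.6g]\n",
                length(d), min(d), max(d)))
  show <- utils::head(x$labels, 6L)
  cat("  taxa:", paste(show, collapse = ", "),
      if (x$n > 6L) "..." else "", "\n")
  invisible(x)
}

## one distance, by 1-based taxon index, any order
dist_cell <- function(m, i, k) {
  if (i == k) return(0)
  if (i < k) { tmp <- i; i <- k; k <- tmp }
  distances(m)[tri_idx(i, k)]
}

#' Per-row distance sums
#'
#' Computes `S_i`, the sum of distances from taxon `i` to every other
#' taxon, always in double precision whatever the matrix storage mode.
#' These row sums enter the neighbor-joining criterion
#' `Q(i,k) = (n-2) D(i,k) - S_i - S_k`.
#'
#' @param m an `nj_dist` object.
#' @return named numeric vector of length `n`.
#' @examples
#' m <- dist_matrix(c(2, 3, 4), labels = c("A", "B", "C"))
#' row_sums(m)  # 5 6 7
#' @export
row_sums <- function(m) {
  stopifnot(inherits(m, "nj_dist"))
  full <- as.matrix(m)
  stats::setNames(rowSums(full), m$labels)
}
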