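#' Parse a Newick tree
#'
#' Light wrapper around [ape::read.tree()] that first checks the string
#' for balanced parentheses and trailing garbage so malformed input fails
#' with a position instead of an obscure parser state. Missing branch
#' lengths default to 0.
#'
#' @param text a single Newick string (";"-terminated).
#' @return an [ape] `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (p in seq_along(chars)) {
    if (chars[p] == "(") depth <- depth + 1L
    if (chars[p] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", p)
    }
  }
  if (depth > 0L) stop("unbalanced '(': ", depth, " unclosed at position ",
                       length(chars))
  semi <- which(chars == ";")
  if (!length(semi)) stop("missing terminating ';' at position ", length(chars))
  if (semi[1L] < length(chars) && nzchar(trimws(substr(text, semi[1L] + 1L,
                                                       nchar(text)))))
    stop("trailing characters after ';' at position ", semi[1L] + 1L)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("Newick parse failure in '", text, "'")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  phy$edge.length[is.na(phy$edge.length)] <- 0
  phy
}

#' Serialize a tree to Newick
#'
#' Branch lengths are printed with enough digits that re-parsing a
#' double-precision tree is exact.
#'
#' @param tree a `phylo` object.
#' @return a Newick string terminated by ";".
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 17)
}

#' Patristic (additive) distance matrix of a tree
#'
#' Sums branch lengths along the unique path between every leaf pair,
#' producing a strictly additive matrix: its quartets satisfy the
#' four-point condition up to accumulation error, and neighbor joining
#' recovers the generating topology exactly from it.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param clamp_negative replace negative branch lengths by 0 before
#'   summing instead of failing.
#' @return an [dist_matrix()] object; taxa in the tree's tip order.
#' @export
patristic_matrix <- function(tree, clamp_negative = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) {
    if (!clamp_negative)
      stop("negative branch length; use clamp_negative = TRUE to zero them")
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  full <- ape::cophenetic.phylo(tree)
  ord <- tree$tip.label
  dist_matrix(full[ord, ord, drop = FALSE], labels = ord)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the symmetric difference of the nontrivial bipartition
#' (internal-edge split) sets of two unrooted trees over the same leaves.
#' The normalized value divides by the total number of nontrivial splits
#' in both trees — `2(n - 3)` when both trees are binary — giving a value
#' in `[0, 1]`. Rooted inputs are unrooted first (the degree-2 root is
#' suppressed), since neighbor joining produces unrooted trees and RF
#' across rooted/unrooted conventions is ill-defined.
#'
#' @param a,b `phylo` objects with identical leaf label sets.
#' @return a list with integer `rf` and numeric `normalized`.
#' @examples
#' t1 <- parse_newick("((A:1,B:1):1,C:1,D:1);")
#' t2 <- parse_newick("((A:1,C:1):1,B:1,D:1);")
#' rf_distance(t1, t2)  # rf = 2, normalized = 1
#' @export
rf_distance <- function(a, b) {
  stopifnot(inherits(a, "phylo"), inherits(b, "phylo"))
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have different leaf label sets")
  if (length(a$tip.label) != length(b$tip.label))
    stop("duplicate leaf labels")
  a <- unroot_safe(a)
  b <- unroot_safe(b)
  rf <- as.integer(phangorn::RF.dist(a, b, check.labels = TRUE))
  denom <- n_internal_splits(a) + n_internal_splits(b)
  list(rf = rf, normalized = if (denom > 0) rf / denom else 0)
}

unroot_safe <- function(t) {
  if (length(t$tip.label) > 2L && ape::is.rooted(t)) ape::unroot(t) else t
}

## nontrivial bipartitions = internal edges of the unrooted tree
n_internal_splits <- function(t) {
  n <- length(t$tip.label)
  sum(t$edge[, 2L] > n)
}
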