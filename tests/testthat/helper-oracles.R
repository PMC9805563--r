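## Independent brute-force oracles used to cross-check the package's
## implementations. Deliberately naive: enumeration and graph traversal,
## no shared code with the functions under test.

## patristic distances by breadth-first path traversal over the edge list
brute_patristic <- function(tree) {
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (src in seq_len(n)) {
    dist <- rep(NA_real_, nnode)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (r in seq_len(NROW(adj[[v]]))) {
        to <- adj[[v]][r, 1L]
        if (is.na(dist[to])) {
          dist[to] <- dist[v] + adj[[v]][r, 2L]
          queue <- c(queue, to)
        }
      }
    }
    out[src, ] <- dist[seq_len(n)]
  }
  out
}

## nontrivial bipartitions as canonical strings: for each internal edge,
## the leaf set below it, reported as the side containing the
## alphabetically first label
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, tips_below))
  }
  anchor <- sort(tree$tip.label)[1L]
  splits <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n) next
    below <- tips_below(child)
    if (length(below) <= 1L || length(below) >= n - 1L) next
    side <- if (anchor %in% below) below else setdiff(tree$tip.label, below)
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

brute_rf <- function(a, b) {
  sa <- tree_splits(a); sb <- tree_splits(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

## four-point condition over all quartets: the two largest of the three
## pairwise-sum combinations must agree
four_point_max_violation <- function(m) {
  full <- as.matrix(m)
  n <- nrow(full)
  worst <- 0
  for (q in utils::combn(n, 4L, simplify = FALSE)) {
    i <- q[1L]; j <- q[2L]; k <- q[3L]; l <- q[4L]
    sums <- sort(c(full[i, j] + full[k, l],
                   full[i, k] + full[j, l],
                   full[i, l] + full[j, k]))
    worst <- max(worst, sums[3L] - sums[2L])
  }
  worst
}

triangle_max_violation <- function(m) {
  full <- as.matrix(m)
  n <- nrow(full)
  worst <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    worst <- max(worst, max(full[i, j] - (full[i, ] + full[, j])))
  worst
}

## reference trace of the descending running-minimum sweep, driven by
## brute-force row minima (valid for the first sweep, when every cache is
## exact); returns the expected rescan count and selected pair
reference_first_sweep <- function(m) {
  full <- as.matrix(m)
  n <- nrow(full)
  S <- rowSums(full)
  rowmin <- rep(Inf, n); rowarg <- rep(NA_integer_, n)
  for (r in 2:n) {
    v <- (n - 2) * full[r, 1:(r - 1)] - S[r] - S[1:(r - 1)]
    rowmin[r] <- min(v)
    rowarg[r] <- which.min(v)
  }
  M <- Inf; rescans <- 0L; fresh <- rep(FALSE, n)
  for (r in n:2) {
    if (rowmin[r] < M) { rescans <- rescans + 1L; fresh[r] <- TRUE }
    if (rowmin[r] < M) M <- rowmin[r]
  }
  sel <- which(fresh & rowmin == M)[1L]
  list(rescans = rescans, row = sel, col = rowarg[sel], M = M)
}

## quick validity audit for an unrooted binary tree over given labels
expect_valid_binary_tree <- function(tree, labels) {
  n <- length(labels)
  expect_setequal(tree$tip.label, labels)
  expect_equal(nrow(tree$edge), 2L * n - 3L)
  expect_equal(tree$Nnode, n - 2L)
  tab <- tabulate(tree$edge, nbins = n + tree$Nnode)
  expect_true(all(tab[seq_len(n)] == 1L))         # leaves pendant
  expect_true(all(tab[-seq_len(n)] == 3L))        # internals degree 3
}

rand_int <- function() sample.int(1e6, 1L)
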