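## Seeded fixture generators. All randomness goes through R's default
## Mersenne-Twister stream, isolated so the caller's RNG state is
## untouched; the same (parameters, seed) always yields the same object.

with_isolated_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random unrooted binary tree
#'
#' Grows a tree over leaves `t1..tn` by repeatedly attaching the next
#' leaf to a uniformly chosen edge, then draws every branch length
#' i.i.d. uniform from `length_range`. Deterministic in `(n, seed)`.
#'
#' @param n number of leaves, `>= 2`.
#' @param seed integer seed.
#' @param length_range `c(lo, hi)` with `0 < lo <= hi`; branch-length
#'   units are those of the distances the tree will generate.
#' @return an unrooted binary `phylo`.
#' @export
random_binary_tree <- function(n, seed, length_range = c(0.1, 2)) {
  if (n < 2L) stop("a tree needs at least 2 leaves")
  lo <- length_range[1L]; hi <- length_range[2L]
  if (!(lo > 0 && lo <= hi)) stop("need 0 < lo <= hi in length_range")
  with_isolated_seed(seed, {
    if (n == 2L) {
      len <- stats::runif(2L, lo, hi)
      return(parse_newick(sprintf("(t1:%.17g,t2:%.17g);", len[1L], len[2L])))
    }
    ## rtopology grows by random edge attachment: uniform over labelled
    ## topologies; then unroot and re-draw lengths in the requested range
    phy <- ape::rtopology(n, rooted = FALSE, tip.label = paste0("t", seq_len(n)))
    phy$edge.length <- stats::runif(nrow(phy$edge), lo, hi)
    phy
  })
}

#' Strictly additive distance matrix
#'
#' Patristic matrix of a [random_binary_tree()]: distances realizable
#' exactly as path lengths on a tree, hence satisfying the four-point
#' condition. Neighbor joining is exact on such matrices, which makes
#' them the ground-truth fixtures for the oracle-equivalence suites.
#'
#' @inheritParams random_binary_tree
#' @return an [dist_matrix()] object (taxa in tree tip order).
#' @export
additive_matrix <- function(n, seed, length_range = c(0.1, 2)) {
  patristic_matrix(random_binary_tree(n, seed, length_range))
}

#' Metric distance matrix from random points
#'
#' Draws `n` i.i.d. standard-normal points in `dim` dimensions and takes
#' pairwise Euclidean or cosine (`1 - cos`) distances. The Euclidean
#' output satisfies the triangle inequality exactly — the premise under
#' which the dynamic variant's cached bounds are justified; cosine
#' emulates the high-dimensional expression-profile matrices the method
#' targets.
#'
#' @param n number of points, `>= 2`.
#' @param seed integer seed.
#' @param dim embedding dimension.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return an [dist_matrix()] object with labels `t1..tn`.
#' @export
metric_matrix <- function(n, seed, dim = 8, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (n < 2L) stop("need n >= 2")
  pts <- with_isolated_seed(seed, matrix(stats::rnorm(n * dim), n, dim))
  full <- point_distances(pts, metric)
  dist_matrix(full, labels = paste0("t", seq_len(n)))
}

point_distances <- function(pts, metric) {
  if (metric == "euclidean") {
    as.matrix(stats::dist(pts))
  } else {
    nrm <- sqrt(rowSums(pts^2))
    cs <- (pts %*% t(pts)) / outer(nrm, nrm)
    d <- 1 - cs
    d[d < 0] <- 0
    diag(d) <- 0
    (d + t(d)) / 2
  }
}

#' Multiplicative perturbation of a matrix
#'
#' Multiplies every stored cell by an independent uniform draw from
#' `[1 - noise, 1 + noise]`, moving an additive matrix away from
#' additivity by a controlled amount while preserving non-negativity.
#' `noise = 0` is the identity.
#'
#' @param m an [dist_matrix()] object in a floating mode.
#' @param noise amplitude in `[0, 1)`.
#' @param seed integer seed.
#' @return a perturbed `nj_dist`.
#' @export
perturb <- function(m, noise, seed) {
  stopifnot(inherits(m, "nj_dist"))
  if (noise < 0 || noise >= 1) stop("need 0 <= noise < 1")
  if (noise == 0) return(m)
  f <- with_isolated_seed(seed,
                          stats::runif(length(m$x), 1 - noise, 1 + noise))
  new_nj_dist(m$x * f, m$labels)
}

#' Clustered (Gaussian-mixture) distance matrix
#'
#' Euclidean distances among points drawn from `k_clusters`
#' well-separated Gaussian blobs (centers on a scaled simplex, unit
#' within-cluster spread, separation 20). Hierarchically structured
#' inputs like these are the regime where the dynamic search examines a
#' near-constant number of rows per iteration.
#'
#' @param n number of points.
#' @param k_clusters number of mixture components, `1 <= k <= n`.
#' @param seed integer seed.
#' @param dim embedding dimension.
#' @return an [dist_matrix()] object.
#' @export
clustered_matrix <- function(n, k_clusters, seed, dim = 8) {
  if (k_clusters < 1L || k_clusters > n) stop("need 1 <= k_clusters <= n")
  pts <- with_isolated_seed(seed, {
    centers <- matrix(stats::rnorm(k_clusters * dim), k_clusters, dim)
    centers <- centers / sqrt(rowSums(centers^2)) * 20
    assign_k <- rep_len(seq_len(k_clusters), n)
    centers[assign_k, , drop = FALSE] +
      matrix(stats::rnorm(n * dim), n, dim)
  })
  dist_matrix(point_distances(pts, "euclidean"),
              labels = paste0("t", seq_len(n)))
}

#' Adversarial equal-distance star matrix
#'
#' All off-diagonal distances equal `c`: the patristic matrix of a star
#' tree with uniform pendant lengths `c/2`. Every join criterion ties at
#' every iteration and each contraction lowers all criteria below every
#' cached bound, so the dynamic search must re-examine essentially every
#' row — the worst-case regime where its per-iteration row count `d`
#' approaches `n`.
#'
#' @param n number of taxa.
#' @param c the common distance (default 1).
#' @return an [dist_matrix()] object.
#' @export
star_matrix <- function(n, c = 1) {
  if (n < 2L) stop("need n >= 2")
  new_nj_dist(rep(c, n * (n - 1L) / 2L), paste0("t", seq_len(n)))
}
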