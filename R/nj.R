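## exhaustive global minimum of the join criterion, by an arithmetic
## route (outer sums over the full matrix) independent of crit_row();
## used by the diagnostic cross-checks
brute_force_min <- function(st) {
  m <- st$m
  act <- seq_len(m)
  Qf <- (m - 2) * st$D[act, act] - outer(st$S[act], st$S[act], "+")
  min(Qf[lower.tri(Qf)])
}

brute_force_row_min <- function(st, r) {
  ks <- seq_len(r - 1L)
  min((st$m - 2) * st$D[r, ks] - (st$S[r] + st$S[ks]))
}

## exact full-scan selection: smallest criterion, ties to the smallest
## storage row then the smallest column
canonical_select <- function(st) {
  best <- Inf; r0 <- NA_integer_; k0 <- NA_integer_
  for (r in seq_len(st$m)[-1L]) {
    v <- crit_row(st, r)
    w <- which.min(v)
    if (v[w] < best) { best <- v[w]; r0 <- r; k0 <- w }
  }
  c(st$h[r0], st$h[k0])
}

nj_run <- function(m, method = c("nj", "dnj", "hnj"),
                   clamp_negative = FALSE,
                   check_lower_bound = FALSE, check_sweep = FALSE) {
  method <- match.arg(method)
  st <- nj_state(m, clamp_negative = clamp_negative)
  qc <- if (method != "nj" && st$m > 3L) init_cache(st) else NULL
  violations <- list()
  sweep_max_disc <- 0
  iterations <- 0L
  active_trace <- integer(0)

  while (st$m > 3L) {
    active_trace <- c(active_trace, st$m)
    if (method == "dnj" && check_lower_bound) {
      tol <- 1e-9 * st$m * max(st$D[seq_len(st$m), seq_len(st$m)])
      for (r in seq_len(st$m)[-1L]) {
        bf <- brute_force_row_min(st, r)
        slack <- qc$Q[r] - bf
        if (slack > tol)
          violations[[length(violations) + 1L]] <-
            list(row = st$h[r], partner = qc$J[r], slack = slack)
      }
    }
    pair <- switch(method,
                   nj  = canonical_select(st),
                   dnj = sweep_min(qc, st),
                   hnj = hnj_select(qc, st))
    if (method == "dnj" && check_sweep) {
      disc <- abs(qc$last_M - brute_force_min(st))
      if (disc > sweep_max_disc) sweep_max_disc <- disc
    }
    z <- update_after_join(st, pair[2L], pair[1L])
    if (method == "dnj") repair_cache(qc, st, z)
    if (method == "hnj") hnj_update(qc, st, z)
    iterations <- iterations + 1L
  }
  tree <- assemble_tree(st, terminal_resolution(st))

  report <- list(
    method = method,
    n = st$n0,
    iterations = iterations,
    rescans = if (is.null(qc)) NA_integer_ else qc$rescans,
    sweep_rescans = if (is.null(qc)) NA_integer_ else qc$sweep_rescans,
    repair_scans = if (is.null(qc)) NA_integer_ else qc$repair_scans,
    rescans_per_iter = if (is.null(qc)) integer(0) else qc$rescans_per_iter,
    mean_rescans_per_iter =
      if (is.null(qc) || iterations == 0L) NA_real_
      else qc$sweep_rescans / iterations,
    mean_active_rows =
      if (iterations == 0L) NA_real_ else mean(active_trace),
    n_lower_bound_violations = length(violations),
    lower_bound_violations = violations,
    max_sweep_discrepancy = if (method == "dnj" && check_sweep)
      sweep_max_disc else NA_real_,
    rng = "none: all three variants are deterministic")
  attr(tree, "nj_report") <- report
  tree
}

#' Canonical neighbor joining (exhaustive search)
#'
#' The Saitou-Nei agglomeration with the full quadratic criterion scan at
#' every iteration: repeatedly joins the global minimizer of
#' `Q(i,k) = (n-2) D(i,k) - S_i - S_k`, assigns Studier-Keppler branch
#' lengths, and contracts the matrix with
#' `D(i,z) = (D(x,i) + D(i,y) - D(x,y)) / 2` until three nodes remain,
#' which are resolved exactly against their three pairwise distances
#' (two taxa split their single distance evenly). Ties are broken toward
#' the smallest storage row, then the smallest column, the same rule all
#' variants share, so "the exact NJ tree" is well defined. O(n^3) time —
#' this function is the correctness oracle for [dnj()] and [hnj()].
#'
#' @param m an [dist_matrix()] object with `n >= 2` taxa.
#' @param clamp_negative clamp negative branch lengths to zero (off by
#'   default; clamping changes trees and breaks oracle equality).
#' @return an unrooted `phylo` tree with `2n - 3` edges (`n >= 3`); a run
#'   report is attached as attribute `"nj_report"` (see [nj_report()]).
#' @examples
#' m <- dist_matrix(c(2, 3, 4), labels = c("A", "B", "C"))
#' write_newick(canonical_nj(m))
#' @seealso [dnj()], [hnj()]
#' @export
canonical_nj <- function(m, clamp_negative = FALSE) {
  nj_run(m, "nj", clamp_negative = clamp_negative)
}

#' Dynamic neighbor joining (exact, cached search)
#'
#' Produces the same tree as [canonical_nj()] — identical topology and
#' branch lengths under the shared tie-break rule — while replacing the
#' quadratic per-iteration search with a cached one: each row remembers
#' its minimum criterion, a descending running-minimum sweep rescans only
#' rows whose cache could beat the current best ([sweep_min()]), and the
#' cache is repaired in linear time after each join ([repair_cache()]).
#' Rescanning `d` rows per iteration gives O(d n^2) total time; on
#' clustered data `d` stays near-constant, while on degenerate
#' equal-distance inputs it approaches `n` and the algorithm falls back
#' to cubic behavior.
#'
#' The skip logic is justified for non-negative distances satisfying the
#' triangle inequality, under which criteria only weaken as the matrix
#' contracts, so cached minima stay lower bounds. `check_lower_bound`
#' verifies that property against a brute-force row minimum at every
#' iteration, recording (never asserting away) any violation;
#' `check_sweep` cross-checks every sweep's running minimum against an
#' exhaustive scan. Both are diagnostics for tests and cost O(n^2) per
#' iteration.
#'
#' @inheritParams canonical_nj
#' @param check_lower_bound record cached-bound violations per iteration.
#' @param check_sweep record the worst |sweep minimum - exhaustive
#'   minimum| across iterations.
#' @return an unrooted `phylo`; attribute `"nj_report"` carries
#'   `iterations`, `rescans` (the paper-facing search effort `d`),
#'   per-iteration rescan counts, and the diagnostic tallies.
#' @examples
#' m <- additive_matrix(16, seed = 1)
#' t1 <- dnj(m)
#' rf_distance(t1, canonical_nj(m))$rf  # 0: identical topology
#' @export
dnj <- function(m, clamp_negative = FALSE,
                check_lower_bound = FALSE, check_sweep = FALSE) {
  nj_run(m, "dnj", clamp_negative = clamp_negative,
         check_lower_bound = check_lower_bound, check_sweep = check_sweep)
}

#' Heuristic neighbor joining (quadratic time)
#'
#' Joins the minimum of the cached criterion vector directly, never
#' re-searching rows: after each join the caches are updated only against
#' the remembered partner (re-evaluated at the current state) and the
#' newly formed node ([hnj_update()]), which caps the total work at
#' O(n^2). On strictly additive matrices a completed join can never
#' create a better alternative than the remembered row minima, so the
#' output equals the exact NJ tree; on noisy matrices the tree is a valid
#' binary unrooted tree that may deviate from exact NJ, with the
#' deviation growing with the distance from additivity.
#'
#' @inheritParams canonical_nj
#' @return an unrooted `phylo`; attribute `"nj_report"` records the
#'   stale-partner rescans performed.
#' @examples
#' m <- additive_matrix(32, seed = 7)
#' rf_distance(hnj(m), canonical_nj(m))$rf  # 0 on additive input
#' @export
hnj <- function(m, clamp_negative = FALSE) {
  nj_run(m, "hnj", clamp_negative = clamp_negative)
}

#' Run report of an NJ variant
#'
#' @param tree a tree returned by [canonical_nj()], [dnj()] or [hnj()].
#' @return the attached report list: `method`, `n`, `iterations`,
#'   `rescans`, `sweep_rescans`, `repair_scans`, `rescans_per_iter`,
#'   `mean_rescans_per_iter`, `mean_active_rows`,
#'   `n_lower_bound_violations`, `lower_bound_violations`,
#'   `max_sweep_discrepancy`.
#' @export
nj_report <- function(tree) attr(tree, "nj_report")
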