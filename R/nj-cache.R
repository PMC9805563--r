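#' Initialize the per-row criterion cache
#'
#' Scans every storage row once and records `Q_i`, the minimum join
#' criterion of row `i` over its columns `k < i`, together with the
#' argmin partner handle `J_i` (ties broken toward the smallest column).
#' Row 1 stores no pairs and carries `Q = Inf`. The rescan counter starts
#' at `n - 1`, one initial scan per nonempty row.
#'
#' The cached `Q_i` is the load-bearing quantity of the dynamic variant:
#' because join criteria only weaken as the matrix contracts (for
#' non-negative distances satisfying the triangle inequality), a cached
#' row minimum remains a lower bound on the row's current criteria, so a
#' row whose cache cannot beat the running minimum can be skipped without
#' rescanning it.
#'
#' @param state an [nj_state()] environment.
#' @return an environment of class `"nj_qcache"` with fields `Q`, `J`,
#'   `stale`, `rescans` (cumulative full row scans), `sweep_rescans`,
#'   `repair_scans`, `z_slot`, `last_M`.
#' @export
init_cache <- function(state) {
  st <- state
  n0 <- st$n0
  qc <- new.env(parent = emptyenv())
  qc$Q <- rep(Inf, n0)
  qc$J <- rep(NA_integer_, n0)
  qc$stale <- rep(FALSE, n0)
  for (r in seq_len(st$m)[-1L]) {
    v <- crit_row(st, r)
    w <- which.min(v)
    qc$Q[r] <- v[w]
    qc$J[r] <- st$h[w]
  }
  qc$rescans <- st$m - 1L
  qc$sweep_rescans <- 0L
  qc$repair_scans <- 0L
  qc$rescans_per_iter <- integer(0)
  qc$z_slot <- NA_integer_
  qc$last_M <- NA_real_
  class(qc) <- "nj_qcache"
  qc
}

#' Running-minimum sweep for the exact best join
#'
#' Walks the storage rows in descending order maintaining a running
#' minimum `M`. A row is fully rescanned — refreshing its `Q_i` and
#' partner — only when its cached `Q_i < M` (strict, as in the dynamic
#' recursion); `M` then absorbs the row's `Q_i`. Because caches are lower
#' bounds, a skipped row cannot hide a better join, so after the sweep
#' `M` equals the exact global minimum criterion. On the first sweep
#' after a join, `M` starts at the fresh new-node row's `Q_z` rather
#' than at infinity, since the new node frequently hosts the next best
#' join.
#'
#' The returned pair always comes from a row refreshed in this sweep (or
#' the fresh new-node row), so the partner is never stale at selection;
#' among refreshed rows tying at `M`, the smallest storage row wins, and
#' within a row the smallest column (the shared deterministic tie-break).
#'
#' @param cache an [init_cache()] environment; modified in place
#'   (`sweep_rescans`, `last_M`).
#' @param state the matching [nj_state()].
#' @return `c(i, j)`: the handles of the exact argmin pair, `i` the row
#'   node and `j` its partner.
#' @export
sweep_min <- function(cache, state) {
  st <- state; qc <- cache
  m <- st$m
  if (m == 2L) return(c(st$h[2L], st$h[1L]))
  Q <- qc$Q
  fresh <- rep(FALSE, m)
  if (!is.na(qc$z_slot) && qc$z_slot <= m) {
    M <- Q[qc$z_slot]
    fresh[qc$z_slot] <- TRUE
  } else M <- Inf
  nre <- 0L
  for (r in m:2L) {
    if (Q[r] < M) {
      v <- crit_row(st, r)
      w <- which.min(v)
      Q[r] <- v[w]
      qc$J[r] <- st$h[w]
      qc$stale[r] <- FALSE
      fresh[r] <- TRUE
      nre <- nre + 1L
    }
    if (Q[r] < M) M <- Q[r]
  }
  qc$Q[seq_len(m)] <- Q[seq_len(m)]
  qc$sweep_rescans <- qc$sweep_rescans + nre
  qc$rescans <- qc$rescans + nre
  qc$rescans_per_iter <- c(qc$rescans_per_iter, nre)
  qc$last_M <- M
  cand <- which(fresh & Q[seq_len(m)] == M)
  r0 <- cand[1L]
  c(st$h[r0], qc$J[r0])
}

#' Linear-time cache repair after a join
#'
#' Restores the lower-bound property of the cache after
#' [update_after_join()]: the new node's row is scanned in full, and for
#' every higher-indexed row the new-node criterion
#' `(n-2) D(i,z) - S_i - S_z` is folded into the cached minimum (the
#' partner becomes `z` where the new term wins). Rows whose remembered
#' partner was retired by the join keep their `Q` — still a valid lower
#' bound — with the partner flagged stale; the sweep refreshes any such
#' row before it can be selected.
#'
#' Storage compaction moves the last live row into the freed slot, which
#' migrates that node's pairings with higher-indexed rows into columns
#' those rows' caches never scanned; the repair therefore also folds the
#' moved node's criterion into every higher-indexed row, keeping every
#' stored pair covered by some cached bound. Total work stays linear in
#' the number of live rows.
#'
#' @param cache the [init_cache()] environment; modified in place.
#' @param state the matching [nj_state()]; its `last_join` field
#'   identifies the new node's slot and the compaction move.
#' @param z the new node handle returned by [update_after_join()].
#' @return the cache, invisibly.
#' @export
repair_cache <- function(cache, state, z) {
  st <- state; qc <- cache
  lj <- st$last_join
  if (is.null(lj) || lj$z != z) stop("repair_cache: stale join info")
  m <- st$m
  k <- lj$zslot
  mv <- lj$moved_slot

  ## cache rows move with the compaction
  if (!is.na(mv)) {
    old_last <- m + 1L
    qc$Q[mv] <- qc$Q[old_last]
    qc$J[mv] <- qc$J[old_last]
    qc$stale[mv] <- qc$stale[old_last]
  }
  ## partners consumed by the join are stale (Q kept: still a lower bound)
  live <- seq_len(m)
  dead <- !is.na(qc$J[live]) & (qc$J[live] == lj$hx | qc$J[live] == lj$hy)
  qc$stale[live][dead] <- TRUE

  ## full scan of the new node's row
  if (k > 1L) {
    v <- crit_row(st, k)
    w <- which.min(v)
    qc$Q[k] <- v[w]
    qc$J[k] <- st$h[w]
  } else {
    qc$Q[k] <- Inf
    qc$J[k] <- NA_integer_
  }
  qc$stale[k] <- FALSE
  qc$repair_scans <- qc$repair_scans + 1L

  ## fold the new-node terms into the rows below it
  fold_column <- function(col) {
    rs <- if (col < m) (col + 1L):m else integer(0)
    if (!length(rs)) return(invisible())
    tv <- crit_terms(st$D[rs, col], st$S[rs], st$S[col], m)
    win <- tv < qc$Q[rs]
    if (any(win)) {
      qc$Q[rs][win] <- tv[win]
      qc$J[rs][win] <- st$h[col]
      qc$stale[rs][win] <- FALSE
    }
  }
  fold_column(k)
  ## and the moved node's terms (its pairs migrated into new columns)
  if (!is.na(mv)) fold_column(mv)

  qc$z_slot <- k
  invisible(qc)
}

#' Heuristic cache update (no row search)
#'
#' The quadratic-time variant's replacement for sweep-and-repair: after a
#' join, the new node's row is scanned once; every other row's cached
#' criterion is re-evaluated against its remembered partner with the
#' current node count and row sums, and compared with the new-node term —
#' whichever is smaller wins the cache. No other rescans happen, so the
#' cached values are heuristic row minima, not guaranteed bounds. A row
#' whose remembered partner was consumed by the join (and is not replaced
#' by the new node's term) is rescanned once, so a join is never made
#' through a retired partner; at most every row is rescanned once per
#' iteration, preserving quadratic behavior in practice.
#'
#' @inheritParams repair_cache
#' @return the cache, invisibly.
#' @export
hnj_update <- function(cache, state, z) {
  st <- state; qc <- cache
  lj <- st$last_join
  if (is.null(lj) || lj$z != z) stop("hnj_update: stale join info")
  m <- st$m
  k <- lj$zslot
  mv <- lj$moved_slot

  if (!is.na(mv)) {
    old_last <- m + 1L
    qc$Q[mv] <- qc$Q[old_last]
    qc$J[mv] <- qc$J[old_last]
  }

  ## full scan of the new node's row
  if (k > 1L) {
    v <- crit_row(st, k)
    w <- which.min(v)
    qc$Q[k] <- v[w]
    qc$J[k] <- st$h[w]
  } else {
    qc$Q[k] <- Inf
    qc$J[k] <- NA_integer_
  }
  qc$repair_scans <- qc$repair_scans + 1L

  rows <- setdiff(seq_len(m)[-1L], k)
  if (length(rows)) {
    js <- qc$J[rows]
    dead <- is.na(js) | js == lj$hx | js == lj$hy
    ## stale partner: one full rescan of that row
    for (r in rows[dead]) {
      v <- crit_row(st, r)
      w <- which.min(v)
      qc$Q[r] <- v[w]
      qc$J[r] <- st$h[w]
      qc$rescans <- qc$rescans + 1L
      qc$sweep_rescans <- qc$sweep_rescans + 1L
    }
    ## live partner: re-evaluate the remembered pair at the current state
    alive <- rows[!dead]
    if (length(alive)) {
      js <- st$slot[qc$J[alive]]
      qc$Q[alive] <- crit_terms(st$D[cbind(alive, js)], st$S[alive],
                                st$S[js], m)
    }
    ## fold the new-node terms for rows below it
    rs <- rows[rows > k]
    if (length(rs)) {
      tv <- crit_terms(st$D[rs, k], st$S[rs], st$S[k], m)
      win <- tv < qc$Q[rs]
      if (any(win)) {
        qc$Q[rs][win] <- tv[win]
        qc$J[rs][win] <- z
      }
    }
  }
  qc$z_slot <- k
  invisible(qc)
}

## heuristic selection: argmin of the cached Q vector, smallest slot on ties
hnj_select <- function(cache, state) {
  st <- state; qc <- cache
  m <- st$m
  if (m == 2L) return(c(st$h[2L], st$h[1L]))
  r0 <- which.min(qc$Q[seq_len(m)])
  c(st$h[r0], qc$J[r0])
}
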