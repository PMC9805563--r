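#' Live neighbor-joining state
#'
#' Creates the mutable state all three NJ variants operate on: the live
#' (shrinking) distance matrix, the per-row sums `S` kept in double
#' precision whatever the matrix storage mode, a handle for every live
#' node, and the join log. Handles `1..n` are the input taxa in label
#' order; each join creates a fresh handle. Storage rows are compacted on
#' every join — the new node overwrites the storage row of the
#' smaller-indexed parent and the last live row moves into the row of the
#' larger-indexed parent — so the triangle stays dense and shrinking.
#'
#' The state is an environment and is modified in place by
#' [update_after_join()] and the cache operations; this mirrors how the
#' algorithm mutates one triangular matrix in O(n^2) space.
#'
#' @param m an [dist_matrix()] object, `n >= 2`.
#' @param clamp_negative clamp negative branch lengths to zero when
#'   recording joins. Off by default: reporting lengths as computed keeps
#'   oracle comparisons between NJ variants exact.
#' @return an environment of class `"nj_state"`.
#' @export
nj_state <- function(m, clamp_negative = FALSE) {
  stopifnot(inherits(m, "nj_dist"))
  if (m$n < 2L) stop("neighbor joining needs at least 2 taxa")
  n <- m$n
  st <- new.env(parent = baseenv())
  st$n0 <- n
  st$labels <- m$labels
  st$precision <- m$precision
  st$scale <- m$scale
  st$quant_L <- switch(m$precision, uint8 = 255, uint16 = 65535, NULL)
  st$D <- as.matrix(m)
  dimnames(st$D) <- NULL
  if (m$precision == "float")   # storage is single precision; S stays double
    st$D[] <- snap_precision(st, as.vector(st$D))
  st$S <- rowSums(st$D)
  st$m <- n
  st$h <- seq_len(n)                    # handle at each storage slot
  st$slot <- rep(NA_integer_, 2L * n)   # storage slot of each handle
  st$slot[seq_len(n)] <- seq_len(n)
  st$next_h <- n + 1L
  st$children <- vector("list", 2L * n)
  st$joins <- list()
  st$clamp <- isTRUE(clamp_negative)
  class(st) <- "nj_state"
  st
}

## the one shared arithmetic form of the join criterion:
## (n-2)*D - S_i - S_k, evaluated left to right so every code path
## (oracle scan, cache scan, repair fold) rounds identically
crit_terms <- function(d, si, sk, m) (m - 2) * d - si - sk

## criterion of storage row r against all columns k < r
crit_row <- function(st, r) {
  ks <- seq_len(r - 1L)
  crit_terms(st$D[r, ks], st$S[r], st$S[ks], st$m)
}

## snap new distances to the matrix storage precision
snap_precision <- function(st, v) {
  if (!is.null(st$quant_L)) {
    cells <- pmin(pmax(round_half_up(v / st$scale), 0), st$quant_L)
    cells * st$scale
  } else if (st$precision == "float") {
    readBin(writeBin(v, raw(), size = 4L), "numeric", size = 4L,
            n = length(v))
  } else v
}

#' Join criterion for one node pair
#'
#' Computes `Q(i,k) = (n-2) D(i,k) - S_i - S_k` in double precision for
#' two live nodes, where `n` is the current number of live nodes. The
#' global minimizer of this criterion defines the canonical NJ join.
#'
#' @param state an [nj_state()] environment.
#' @param i,k distinct live node handles.
#' @return the criterion value (lower is better).
#' @export
q_value <- function(state, i, k) {
  si <- state$slot[i]; sk <- state$slot[k]
  if (is.na(si) || is.na(sk)) stop("q_value: node not live")
  if (si == sk) stop("q_value: i and k must differ")
  crit_terms(state$D[si, sk], state$S[si], state$S[sk], state$m)
}

#' Branch lengths for a prospective join
#'
#' Studier-Keppler lengths for joining `x` and `y` into a new node `z`:
#' `bx = D(x,y)/2 + (S_x - S_y) / (2(n-2))` and `by = D(x,y) - bx`.
#' Negative values are reported as computed unless the state was created
#' with `clamp_negative = TRUE`.
#'
#' @param state an [nj_state()] environment with at least 3 live nodes.
#' @param x,y live node handles.
#' @return numeric `c(bx, by)`.
#' @export
branch_lengths <- function(state, x, y) {
  m <- state$m
  if (m < 3L) stop("branch_lengths needs >= 3 live nodes")
  sx <- state$slot[x]; sy <- state$slot[y]
  if (is.na(sx) || is.na(sy)) stop("branch_lengths: node not live")
  d <- state$D[sx, sy]
  bx <- d / 2 + (state$S[sx] - state$S[sy]) / (2 * (m - 2))
  by <- d - bx
  if (state$clamp) c(max(bx, 0), max(by, 0)) else c(bx, by)
}

#' Join two nodes and contract the matrix
#'
#' Performs one agglomeration step: records the join with its branch
#' lengths, computes the new node's distances
#' `D(i,z) = (D(x,i) + D(i,y) - D(x,y)) / 2` to every other live node
#' (re-snapped to the storage precision, saturating at the top level in
#' the integer modes), updates the row sums incrementally in linear time
#' (`S_i <- S_i - D(x,i) - D(i,y) + D(i,z)`), retires `x` and `y`, and
#' compacts storage: `z` takes the slot of `min(x,y)` and the last live
#' row moves into the slot of `max(x,y)`.
#'
#' Details of the compaction are left in `state$last_join`
#' (`z`, `zslot`, `moved_slot`, retired handles) for the cache-repair
#' steps of the dynamic and heuristic variants.
#'
#' @param state an [nj_state()] environment; modified in place.
#' @param x,y distinct live node handles.
#' @return the new node's handle, invisibly.
#' @export
update_after_join <- function(state, x, y) {
  st <- state
  sx <- st$slot[x]; sy <- st$slot[y]
  if (is.na(sx) || is.na(sy) || sx == sy) stop("invalid join pair")
  ## orient so that x sits at the smaller storage slot (the column)
  if (sx > sy) { tmp <- x; x <- y; y <- tmp; tmp <- sx; sx <- sy; sy <- tmp }
  m <- st$m
  b <- branch_lengths(st, x, y)
  act <- seq_len(m)
  di <- st$D[sy, act]; dk <- st$D[sx, act]; dxy <- st$D[sy, sx]
  dz <- (di + dk - dxy) / 2
  dz[c(sx, sy)] <- 0
  dz <- snap_precision(st, dz)

  S_new <- st$S[act] - di - dk + dz
  S_new[sx] <- sum(dz)

  z <- st$next_h; st$next_h <- z + 1L
  st$children[[z]] <- list(x = x, y = y, bx = b[1L], by = b[2L])
  st$joins[[length(st$joins) + 1L]] <-
    list(x = x, y = y, z = z, bx = b[1L], by = b[2L])

  ## write the new row/column and compact inside the state environment:
  ## subassigning through st$D would duplicate the whole matrix on every
  ## join (cubic memory traffic); evaluated in st, D is modified in place
  st$.j <- list(sx = sx, sy = sy, act = act, dz = dz, m = m)
  eval(quote({
    D[.j$sx, .j$act] <- .j$dz
    D[.j$act, .j$sx] <- .j$dz
    if (.j$sy < .j$m) {
      D[.j$sy, .j$act] <- D[.j$m, .j$act]
      D[.j$act, .j$sy] <- D[.j$act, .j$m]
      D[.j$sy, .j$sy] <- 0
    }
  }), st)
  rm(".j", envir = st)

  st$slot[x] <- NA_integer_; st$slot[y] <- NA_integer_
  st$h[sx] <- z
  st$slot[z] <- sx

  moved <- NA_integer_
  if (sy < m) {                    # last live row dropped into y's slot
    hm <- st$h[m]
    st$h[sy] <- hm
    st$slot[hm] <- sy
    S_new[sy] <- S_new[m]
    moved <- sy
  }
  st$S[seq_len(m - 1L)] <- S_new[seq_len(m - 1L)]
  st$m <- m - 1L
  st$last_join <- list(z = z, zslot = sx, moved_slot = moved,
                       hx = x, hy = y)
  invisible(z)
}

## resolve the last 3 (or 2) live nodes into a hub vertex; returns the
## root entries used by assemble_tree()
terminal_resolution <- function(st) {
  m <- st$m
  if (m == 3L) {
    d12 <- st$D[2L, 1L]; d13 <- st$D[3L, 1L]; d23 <- st$D[3L, 2L]
    len <- c((d12 + d13 - d23) / 2,
             (d12 + d23 - d13) / 2,
             (d13 + d23 - d12) / 2)
    if (st$clamp) len <- pmax(len, 0)
    list(list(h = st$h[1L], len = len[1L]),
         list(h = st$h[2L], len = len[2L]),
         list(h = st$h[3L], len = len[3L]))
  } else if (m == 2L) {
    d <- st$D[2L, 1L]
    list(list(h = st$h[1L], len = d / 2),
         list(h = st$h[2L], len = d / 2))
  } else stop("terminal resolution expects 2 or 3 live nodes, found ", m)
}

## iterative preorder build of an ape phylo from the join structure;
## tips keep handles 1..n as tip numbers, internals are numbered preorder
## from n+1 (the terminal hub is the ape root, degree 3)
assemble_tree <- function(st, root_entries) {
  n <- st$n0
  n_join <- length(st$joins)
  n_edge <- 2L * n_join + length(root_entries)
  edge <- matrix(0L, n_edge, 2L)
  elen <- numeric(n_edge)
  root_id <- n + 1L
  next_internal <- n + 2L
  e <- 0L
  ## stack of (parent ape id, handle, branch length)
  stk_pid <- integer(n_edge); stk_h <- integer(n_edge); stk_len <- numeric(n_edge)
  top <- 0L
  for (entry in rev(root_entries)) {
    top <- top + 1L
    stk_pid[top] <- root_id; stk_h[top] <- entry$h; stk_len[top] <- entry$len
  }
  while (top > 0L) {
    pid <- stk_pid[top]; h <- stk_h[top]; len <- stk_len[top]; top <- top - 1L
    if (h <= n) {
      id <- h
    } else {
      id <- next_internal; next_internal <- next_internal + 1L
      ch <- st$children[[h]]
      top <- top + 1L
      stk_pid[top] <- id; stk_h[top] <- ch$y; stk_len[top] <- ch$by
      top <- top + 1L
      stk_pid[top] <- id; stk_h[top] <- ch$x; stk_len[top] <- ch$bx
    }
    e <- e + 1L
    edge[e, ] <- c(pid, id)
    elen[e] <- len
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = st$labels,
                        Nnode = next_internal - n - 1L),
                   class = "phylo", order = "cladewise")
  phy
}
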