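set.seed(2806)
## the additive 4-taxon reference: A-u:1, B-u:2, u-v:2, C-v:3, D-v:4
ref_tree4 <- function() parse_newick("((A:1,B:2):2,C:3,D:4);")
ref_mat4 <- function() patristic_matrix(ref_tree4())

test_that("row sums and the join criterion follow their definitions", {
  m <- dist_matrix(c(2, 3, 4), labels = c("A", "B", "C"))
  expect_equal(row_sums(m), c(A = 5, B = 6, C = 7))
  expect_equal(unname(row_sums(star_matrix(6, 2))), rep(10, 6))
  expect_equal(unname(row_sums(dist_matrix(5, labels = c("A", "B")))), c(5, 5))

  ## constant 4-taxon matrix: Q = 2*1 - 3 - 3 = -4 for every pair
  st <- nj_state(star_matrix(4, 1))
  for (i in 1:3) for (k in (i + 1):4)
    expect_equal(q_value(st, i, k), -4)

  ## at n = 3 the criterion degenerates to -(sum of all distances)
  st3 <- nj_state(dist_matrix(c(2, 3, 4), labels = c("A", "B", "C")))
  expect_equal(q_value(st3, 1, 2), -9)
  expect_equal(q_value(st3, 2, 3), -9)
  expect_equal(q_value(st3, 1, 3), -9)

  ## on the additive 4-taxon matrix the argmin pair is the cherry (A,B)
  st4 <- nj_state(ref_mat4())
  qs <- sapply(list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)),
               function(p) q_value(st4, p[1], p[2]))
  expect_equal(which.min(qs), 1L)
})

test_that("branch lengths take the Studier-Keppler form", {
  st <- nj_state(ref_mat4())
  b <- branch_lengths(st, 1, 2)          # cherry (A,B)
  expect_equal(b, c(1, 2))               # the generating pendant edges
  expect_equal(sum(b), as.matrix(ref_mat4())["A", "B"])

  ## equal row sums split the distance evenly
  ss <- nj_state(star_matrix(5, 2))
  expect_equal(branch_lengths(ss, 2, 4), c(1, 1))

  ## bx + by = D(x,y) on random states
  for (s in 1:3) {
    m <- metric_matrix(8, seed = s)
    stm <- nj_state(m)
    for (p in list(c(1, 5), c(2, 3), c(7, 8))) {
      b <- branch_lengths(stm, p[1], p[2])
      expect_equal(sum(b), as.matrix(m)[p[1], p[2]])
    }
  }
})

test_that("joining contracts the matrix by the midpoint rule and keeps S consistent", {
  ## handcrafted: D(x,i)=3, D(i,y)=5, D(x,y)=4 -> D(i,z)=2
  full <- matrix(0, 4, 4, dimnames = rep(list(c("x", "y", "i", "j")), 2))
  full["x", "y"] <- 4; full["x", "i"] <- 3; full["i", "y"] <- 5
  full["x", "j"] <- 2; full["y", "j"] <- 6; full["i", "j"] <- 7
  full <- full + t(full)
  st <- nj_state(dist_matrix(full))
  z <- update_after_join(st, 1, 2)
  zi <- st$D[st$slot[z], st$slot[3]]
  expect_equal(zi, 2)                     # (3 + 5 - 4)/2
  expect_equal(st$m, 3L)
  expect_true(all(is.na(st$slot[1:2])))

  ## symmetric case D(x,i)=D(i,y)=D(x,y)=c -> c/2; collinear case -> 0
  stc <- nj_state(star_matrix(4, 3))
  z <- update_after_join(stc, 1, 2)
  expect_equal(stc$D[stc$slot[z], stc$slot[3]], 1.5)
  coll <- matrix(c(0, 4, 1, 4, 0, 3, 1, 3, 0), 3, 3)
  stl <- nj_state(dist_matrix(coll))
  z <- update_after_join(stl, 1, 2)
  expect_equal(stl$D[stl$slot[z], stl$slot[3]], 0)

  ## incremental S equals fresh recomputation at every iteration
  for (s in 1:5) {
    n <- sample(5:30, 1)
    m <- metric_matrix(n, seed = s)
    st <- nj_state(m)
    tol <- 1e-9 * n * max(st$D)
    while (st$m > 3) {
      act <- seq_len(st$m)
      expect_lt(max(abs(st$S[act] - rowSums(st$D[act, act]))), tol)
      pick <- sample(act, 2)
      update_after_join(st, st$h[pick[1]], st$h[pick[2]])
    }
  }
})

test_that("canonical NJ recovers generating trees from additive matrices", {
  out <- canonical_nj(ref_mat4())
  expect_equal(rf_distance(out, ref_tree4())$rf, 0L)
  expect_setequal(round(out$edge.length, 9), c(1, 2, 2, 3, 4))

  for (s in 1:20) {
    n <- sample(4:64, 1)
    tr <- random_binary_tree(n, seed = s)
    out <- canonical_nj(patristic_matrix(tr))
    expect_equal(rf_distance(out, tr)$rf, 0L)
    expect_equal(sort(out$edge.length), sort(tr$edge.length),
                 tolerance = 1e-6)
    expect_valid_binary_tree(out, tr$tip.label)
  }
})

test_that("degenerate sizes terminate by exact resolution", {
  ## n=3: solve a+b=2, a+c=3, b+c=4
  t3 <- canonical_nj(dist_matrix(c(2, 3, 4), labels = c("A", "B", "C")))
  len <- setNames(t3$edge.length[order(t3$edge[, 2])][1:3], t3$tip.label)
  expect_equal(len, c(A = 0.5, B = 1.5, C = 2.5))

  t2 <- canonical_nj(dist_matrix(6, labels = c("A", "B")))
  expect_equal(t2$edge.length, c(3, 3))
  expect_setequal(t2$tip.label, c("A", "B"))

  expect_error(nj_state(dist_matrix(numeric(0), labels = "A")), "at least 2")
})

test_that("canonical NJ topologies agree with an independent NJ implementation", {
  for (s in 1:5) {
    n <- sample(5:40, 1)
    m <- metric_matrix(n, seed = s + 60)
    ours <- canonical_nj(m)
    theirs <- ape::nj(as.dist.nj_dist(m))
    expect_equal(rf_distance(ours, theirs)$rf, 0L)
  }
})

test_that("negative branch lengths are reported unless clamping is requested", {
  ## a strongly non-metric matrix produces a negative NJ branch
  full <- matrix(c(0, 1, 9, 9,
                   1, 0, 9, 9,
                   9, 9, 0, 1,
                   9, 9, 1, 0), 4, 4)
  m <- dist_matrix(full)
  raw <- canonical_nj(m)
  cl <- canonical_nj(m, clamp_negative = TRUE)
  expect_gte(min(cl$edge.length), 0)
  expect_equal(rf_distance(raw, cl)$rf, 0L)
})
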