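---
title: "Dynamic and heuristic neighbor joining: model, machinery, and guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic and heuristic neighbor joining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynnj)
```

## The problem

Neighbor joining (NJ) reconstructs an unrooted phylogenetic tree from a
matrix of pairwise distances. At each step it joins the pair of live nodes
$(i,k)$ minimizing the criterion

$$Q_{i,k} = (n-2)\,D_{i,k} - S_i - S_k, \qquad S_i = \sum_{j \ne i} D_{i,j},$$

where $n$ is the current number of live nodes. The joined pair is replaced
by a new node $z$ whose distances follow the midpoint contraction
$D_{i,z} = (D_{x,i} + D_{i,y} - D_{x,y})/2$, and the procedure repeats until
three nodes remain, which close the unrooted tree exactly. A full search
costs $O(n^2)$ per join and $O(n^3)$ in total, which is prohibitive at the
scale of modern surveillance datasets (10^5–10^6 taxa). This package
implements two accelerations over a lower-triangular distance matrix —
dynamic NJ (`dnj()`), which is exact, and heuristic NJ (`hnj()`), which is
quadratic — together with the canonical search (`canonical_nj()`) that
serves as their correctness oracle.

## Why cached row minima are safe: the lower-bound property

The dynamic variant keeps, for every storage row $i$ of the triangle, the
cached minimum $Q_i = \min_{k<i} Q_{i,k}$ and its argmin partner $J_i$. The
key fact is that for matrices with non-negative entries satisfying the
triangle inequality, a join can only *weaken* criteria: expanding
$\hat{Q}_{i,k}$ after joining $(x,y)$ shows
$Q_{i,j} \le \hat{Q}_{i,k}$ reduces to
$0 \le 2D_{x,y} + (D_{i,x}+D_{x,k}-D_{i,k}) + (D_{i,y}+D_{y,k}-D_{i,k})$,
each bracket non-negative by the triangle inequality. A cached row minimum
from an earlier iteration is therefore a *lower bound* on every current
criterion in that row (new-node terms excepted — they are folded in
explicitly after each join), so a row whose cache cannot beat the running
best needs no rescan.

Whether the contracted matrices produced by the midpoint rule always retain
these premises is a subtle point: the argument is airtight for metric
inputs, and the contraction of a metric need not be re-verified for the
bound to hold at the step where it is used. Rather than assume, `dnj()`
offers `check_lower_bound = TRUE`, which compares every cached value
against a brute-force row minimum at every iteration and *records* (never
hides) violations in the run report; the test suite asserts zero violations
across the metric suite, and oracle equality with `canonical_nj()` is the
ground truth throughout.

## The sweep and the repair

Selection walks rows in descending storage order carrying a running
minimum $M$ (initialized to $\infty$): a row is fully rescanned only when
its cached $Q_i < M$ (strictly), after which $M$ absorbs $Q_i$. Since
skipped rows have $Q_i \ge M$ and caches are lower bounds, the final $M$ is
the exact global minimum, reached through some refreshed row. Two
refinements follow the original formulation: after a join, $M$ starts at
the fresh new-node row's $Q_z$ instead of $\infty$ (the new node often
hosts the next join), and the strict inequality means a stale cache tying
$M$ is skipped — harmless, because $M$ is already achieved by a refreshed
row. The number of rescanned rows per iteration, $d$, is the quantity that
drives total cost $O(dn^2)$.

After each join, repair is linear: the new node's row is scanned once, and
$(n-2)D_{i,z} - S_i - S_z$ is folded into every row below it. Rows whose
remembered partner was just retired keep their value (still a bound) with
the partner flagged stale; a stale partner is never joined because
selection only returns refreshed rows.

### Compaction and the migrated-column fold

The triangle is kept dense: the new node overwrites the storage row of the
smaller-indexed parent and the *last* live row drops into the slot of the
larger-indexed one. That move re-homes the moved node's pairings with
higher-indexed rows into columns those rows' caches have never scanned, so
their cached minima would no longer cover every stored pair — a silent gap
in the lower-bound property. The repair step therefore folds the moved
node's criterion into every higher-indexed row as well, one extra
linear-time pass mirroring the new-node fold. This keeps the shrinking
layout and the exactness guarantee at the same time; the run report's
diagnostics confirm the property holds at every iteration.

## The heuristic variant

`hnj()` drops the sweep entirely. Each iteration joins the argmin of the
cached vector directly; afterwards each row's cache is the minimum of just
two terms: the remembered pair re-evaluated with the *current* $n$ and $S$
(the criterion is stated in current-iteration symbols, and freezing the
old scalar would mix row sums from different iterations), and the new-node
term. Rows whose remembered partner was consumed are rescanned once — at
most $n$ rows per iteration, in practice a handful — so total time is
$O(n^2)$. On strictly additive matrices a completed join can never promote
an alternative partner above a remembered row minimum, so the heuristic
output *equals* the exact NJ tree; the suite asserts this across additive
fixtures up to 128 taxa. On noisy matrices the output is still a valid
binary unrooted tree, and its normalized Robinson–Foulds distance from the
exact tree grows with the distance from additivity (probed, not asserted,
in the tests — the rate is data-dependent).

## Determinism and ties

All three variants share one tie-break: among equal-minimum criteria, the
smallest storage row, then the smallest column. All criterion evaluations
go through one arithmetic expression (`(n-2)*d - S_i - S_k`, left to
right), so the oracle scan, the sweep and the repairs round identically
and "the exact NJ tree" is bitwise well defined. With continuous random
distances ties have probability zero; on degenerate inputs (the star
fixture) different *tied* pairs may be chosen by the canonical scan and
the strict-inequality sweep, which both still realize the exact minimum
value.

## Branch lengths, termination, degenerate input

Joins use the Studier–Keppler lengths
$b_x = D_{x,y}/2 + (S_x - S_y)/(2(n-2))$, $b_y = D_{x,y} - b_x$ — the
variant universally used in practice and assumed by cross-tool exactness
comparisons. Negative lengths are reported as computed by default;
`clamp_negative = TRUE` zeroes them at recording time (clamping changes
trees, so it is never on during oracle comparisons). The loop stops at
three live nodes, resolved exactly against their three pairwise distances
(the criterion is degenerate at $n=3$, where all $Q$ tie); two taxa split
their single distance evenly.

## Storage precision

Matrices can be held as double, single (`float`), 2-byte or 1-byte cells.
Quantization maps distances onto the grid `scale = max(D)/L`
(`L` = 255 or 65535) with half-up rounding, so each dequantized cell is
within `scale/2` of the original. Contracted distances are re-snapped to
the same grid, saturating at the top level. Row sums and criteria are
*always* double precision, so the search still discriminates finely among
joins even in byte mode; the cost of byte storage falls mainly on branch
lengths, which inherit the 256-level grid — topology is typically
preserved (the suite checks this for integer matrices that embed exactly),
but interior lengths shift by grid-rounding of the midpoint updates.

## What the synthetic fixtures emulate — and what they do not

- `additive_matrix()`: patristic matrices of random binary trees with
  i.i.d. uniform branch lengths on $[0.1, 2]$ — the regime where NJ (and
  the heuristic) are provably exact, emulating distance matrices derived
  from true trees. Default lengths keep all criteria comfortably away
  from ties while spanning an order of magnitude of edge scales.
- `metric_matrix()`: Euclidean (and cosine) distances of standard-normal
  points in 8 dimensions — metric but far from additive, exercising the
  lower-bound machinery where the additive shortcut does not apply.
- `clustered_matrix()`: a 10-center Gaussian mixture (separation 20, unit
  spread) for the favorable regime where the per-iteration rescan count
  $d$ stays near-constant; `star_matrix()` is the adversarial opposite —
  all distances equal, every criterion tied, every contraction dropping
  all criteria below every cache, forcing $d \approx n$.
- `perturb()` applies independent multiplicative noise
  $U(1-\varepsilon, 1+\varepsilon)$ per cell, giving a controlled dial
  from additivity (heuristic exact) to general dissimilarities.

None of these reproduce the error structure of real pipelines — SNP
distances saturate, cosine distances of expression profiles violate
additivity systematically rather than independently per cell, and real
matrices carry correlated noise from shared evolutionary paths. Passing
the suites therefore demonstrates the algorithmic contracts (exactness,
bounds, regimes), not field accuracy of NJ itself on any particular data
type.

## Numerical choices

- Bookkeeping tolerances scale as $10^{-9}\, n \max D$ (incremental $S$
  vs. fresh recomputation; sweep-vs-brute-force cross-checks), since
  values accumulated along different association orders are not bitwise
  comparable.
- Oracle equality between variants is asserted at RF $= 0$ and branch
  lengths within $10^{-9}$.
- Quantization rounds half-up (deterministic nearest level); an all-zero
  matrix has no defined scale and is rejected.
- Full-matrix symmetry is accepted up to $10^{-6} \max|D|$ (formatted
  files are rarely bit-symmetric); the lower triangle is retained.
- Problem sizes in the shipped suites: oracle equivalence on 200 matrices
  ($n \le 64$ additive, $n \le 40$ metric), heuristic exactness to
  $n = 128$, rescan regimes at $n = 2000$ (clustered) and $n = 256$
  (star). These sizes exercise every code path — including compaction
  moves, stale partners and saturated caches — while keeping the whole
  suite replayable in well under a minute each.

## A worked example

```{r}
tr <- random_binary_tree(24, seed = 11)
m <- patristic_matrix(tr)
out <- dnj(m)
rf_distance(out, tr)$rf            # 0: the generating topology is recovered
rep <- nj_report(out)
c(iterations = rep$iterations, sweep_rescans = rep$sweep_rescans)
```

The report's `sweep_rescans / iterations` is the empirical $d$; compare
`dnj(star_matrix(64))`, where it approaches the live row count.

## Known limitations

- No on-disk matrix mode: the triangle lives in memory, $O(n^2)$ doubles.
- `--threads` in the CLI is interface parity only; computation is serial
  and results are defined by the serial order.
- The heuristic's stale-partner policy (single-row rescan) and the shared
  tie-break are this package's choices; other implementations of the same
  ideas may legitimately produce different trees on non-additive input.
- Float mode stores *distances* in single precision but still computes
  criteria in double; it is a storage model, not a faithful emulation of
  a fully single-precision pipeline.
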