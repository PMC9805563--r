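Package: dynnj
Title: Dynamic and Heuristic Neighbor Joining for Large Distance Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Neighbor-joining phylogenetic tree construction with a
    dynamic row-minimum cache. Implements canonical Saitou-Nei neighbor
    joining as an exactness oracle, dynamic neighbor joining (DNJ) which
    accelerates the join search with cached per-row minima, a running
    minimum sweep and linear-time cache repair while guaranteeing the
    exact NJ tree, and heuristic neighbor joining (HNJ) which drops the
    per-iteration row search for quadratic total time and is exact on
    strictly additive matrices. Reads and writes relaxed lower-triangular
    and full square PHYLIP distance matrices (optionally gzip-compressed),
    supports reduced-precision (float, 2-byte, 1-byte) matrix storage with
    double-precision join criteria, converts Newick trees to additive
    patristic matrices, and validates results with Robinson-Foulds
    distances. Includes seeded generators of additive, metric, perturbed
    and clustered matrices for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
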