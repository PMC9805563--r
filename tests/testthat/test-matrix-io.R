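set.seed(2047)

dist_cell_pub <- function(m, a, b) as.matrix(m)[a, b]
round_half_up_pub <- function(v) floor(v + 0.5)

test_that("relaxed lower-triangular parsing matches the format definition", {
  f <- withr::local_tempfile()
  writeLines(c("3", "A", "B 2.0", "C 3.0 4.0"), f)
  m <- read_phylip(f)
  expect_equal(m$labels, c("A", "B", "C"))
  expect_equal(dist_cell_pub(m, "B", "A"), 2)
  expect_equal(dist_cell_pub(m, "C", "A"), 3)
  expect_equal(dist_cell_pub(m, "C", "B"), 4)

  ## long names and blank lines are tolerated
  writeLines(c("", "2", "a_very_long_taxon_name_indeed 		", "B2 5.5", ""), f)
  m2 <- read_phylip(f)
  expect_equal(m2$labels[1], "a_very_long_taxon_name_indeed")
  expect_equal(m2$x, 5.5)
})

test_that("full dialect parses, checks symmetry, and equals its lower projection", {
  f <- withr::local_tempfile()
  writeLines(c("2", "A 0 5", "B 5 0"), f)
  m <- read_phylip(f, dialect = "full")
  expect_equal(m$n, 2L)
  expect_equal(m$x, 5)

  m4 <- additive_matrix(7, seed = 11)
  write_phylip(m4, f, dialect = "full")
  mf <- read_phylip(f, dialect = "full")
  write_phylip(m4, f, dialect = "relaxed_lower")
  ml <- read_phylip(f, dialect = "relaxed_lower")
  expect_equal(mf$x, ml$x)
  expect_equal(mf$labels, ml$labels)

  writeLines(c("2", "A 0 5", "B 7 0"), f)
  expect_error(read_phylip(f, dialect = "full"), "asymmetric")
})

test_that("malformed input fails naming the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("3", "A", "B 2.0 9.0", "C 3.0 4.0"), f)
  expect_error(read_phylip(f), "line 3.*expected 1")
  writeLines(c("3", "A", "B x", "C 3.0 4.0"), f)
  expect_error(read_phylip(f), "line 3.*non-numeric")
  writeLines(c("3", "A", "B -2.0", "C 3.0 4.0"), f)
  expect_error(read_phylip(f), "negative")
  writeLines(c("nope", "A"), f)
  expect_error(read_phylip(f), "line 1")
})

test_that("gzip input is detected by magic bytes and parses identically", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  m <- additive_matrix(9, seed = 3)
  write_phylip(m, f1)
  write_phylip(m, f2, gzip = TRUE)
  expect_gt(file.size(f1), 0)
  m1 <- read_phylip(f1); m2 <- read_phylip(f2)
  expect_identical(m1$x, m2$x)
  expect_identical(m1$labels, m2$labels)
})

test_that("write-read round trip is the identity in double mode", {
  f <- withr::local_tempfile()
  for (s in 1:5) {
    n <- sample(2:30, 1)
    m <- metric_matrix(n, seed = s)
    for (dia in c("relaxed_lower", "full")) {
      write_phylip(m, f, dialect = dia)
      back <- read_phylip(f, dialect = dia)
      expect_identical(back$x, m$x)
      expect_identical(back$labels, m$labels)
    }
  }
  ## degenerate 1-taxon matrix
  write_phylip(dist_matrix(numeric(0), labels = "A"), f)
  expect_equal(readLines(f), c("1", "A"))
  expect_equal(read_phylip(f)$n, 1L)
})

test_that("quantization uses a max-scaled grid with half-up rounding", {
  m <- dist_matrix(c(2, 5, 10))
  q8 <- quantize(m, "uint8")
  expect_equal(q8$x, c(51, 128, 255))   # 5/10*255 = 127.5 rounds up
  expect_equal(q8$scale, 10 / 255)
  q16 <- quantize(m, "uint16")
  expect_equal(q16$x, round_half_up_pub(c(2, 5, 10) / (10 / 65535)))

  ## integers already on the 0..255 grid embed identically
  mi <- dist_matrix(c(17, 255, 3))
  qi <- quantize(mi, "uint8")
  expect_equal(qi$x, c(17, 255, 3))
  expect_equal(qi$scale, 1)

  ## two-value range: only levels 0 and 255 appear
  m2 <- dist_matrix(c(0, 0, 0, 0, 0, 7))
  expect_setequal(unique(quantize(m2, "uint8")$x), c(0, 255))

  expect_error(quantize(dist_matrix(c(0, 0, 0)), "uint8"), "all-zero")
  expect_error(quantize(quantize(m, "uint8"), "uint8"), "already quantized")
})

test_that("dequantization error is bounded by scale/2 on random matrices", {
  for (s in 1:8) {
    m <- metric_matrix(sample(5:40, 1), seed = s)
    for (p in c("uint8", "uint16")) {
      q <- quantize(m, p)
      err <- max(abs(distances(q) - distances(m)))
      expect_lte(err, q$scale / 2 + 1e-12)
    }
  }
})

test_that("quantized matrices round trip through files as cell*scale", {
  f <- withr::local_tempfile()
  m <- metric_matrix(12, seed = 9)
  q <- quantize(m, "uint8")
  write_phylip(q, f)
  back <- read_phylip(f)
  expect_equal(back$x, distances(q), tolerance = 1e-15)
})
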