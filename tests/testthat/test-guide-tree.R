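test_that("SLINK reproduces brute-force single linkage", {
  ## worked toy: d(1,2)=1, d(1,3)=5, d(2,3)=2
  d <- matrix(c(0, 1, 5, 1, 0, 2, 5, 2, 0), 3, 3)
  tr <- slink_tree(distance_rows(d))
  expect_equal(tr$merge[1, ], c(-1L, -2L))
  expect_equal(tr$height, c(1, 2))

  set.seed(10)
  for (t in 1:15) {
    d <- random_dist(sample(4:50, 1))
    tr <- slink_tree(distance_rows(d))
    expect_equal(sort(tr$height), oracle_single_linkage_heights(d))
    ## cross-check against the established library routine as well
    expect_equal(sort(tr$height),
                 sort(stats::hclust(stats::as.dist(d), "single")$height))
  }
})

test_that("SLINK consumes rows as a stream and validates row lengths", {
  d <- random_dist(8)
  calls <- integer(0)
  stream <- structure(list(k = 8L, labels = NULL, row = function(i) {
    calls <<- c(calls, i)
    if (i == 1L) numeric(0) else d[i, seq_len(i - 1L)]
  }), class = "msa_dist_stream")
  tr <- slink_tree(stream)
  expect_equal(calls, 2:8)                     # one pass, in order
  expect_equal(sort(tr$height), oracle_single_linkage_heights(d))

  bad <- structure(list(k = 3L, labels = NULL,
                        row = function(i) numeric(3)),
                   class = "msa_dist_stream")
  expect_error(slink_tree(bad), "length")
})

test_that("UPGMA matches hand computation and library average linkage", {
  d <- matrix(c(0, 1, 5, 1, 0, 2, 5, 2, 0), 3, 3)
  tr <- upgma_tree(distance_rows(d))
  expect_equal(tr$height, c(1, 3.5))
  expect_equal(tr$merge[1, ], c(-1L, -2L))

  set.seed(11)
  for (t in 1:10) {
    d <- random_dist(sample(4:30, 1))
    tr <- upgma_tree(distance_rows(d))
    expect_equal(sort(tr$height),
                 sort(stats::hclust(stats::as.dist(d), "average")$height))
  }
})

test_that("SLINK and UPGMA coincide on ultrametric inputs", {
  set.seed(12)
  for (t in 1:5) {
    phy <- ape::rcoal(sample(4:20, 1))
    d <- unname(stats::cophenetic(phy))
    expect_equal(sort(slink_tree(distance_rows(d))$height),
                 sort(upgma_tree(distance_rows(d))$height),
                 tolerance = 1e-10)
  }
})

test_that("chained trees have caterpillar shape and closed-form Sackin index", {
  tr <- chained_tree(4, order = 1:4)
  expect_equal(sort(lcsmsa:::leaf_depths(tr), decreasing = TRUE),
               c(3, 3, 2, 1))
  expect_equal(sackin_index(tr)$raw, 9)
  k <- 11
  trk <- chained_tree(k, seed = 5)
  expect_equal(sackin_index(trk)$normalized, (k^2 + k - 2) / (2 * k))
  ## determinism per seed
  expect_identical(chained_tree(9, seed = 3)$merge,
                   chained_tree(9, seed = 3)$merge)
  expect_error(chained_tree(4, order = c(1, 1, 2, 3)), "permutation")
})

test_that("Sackin index: balanced and two-leaf trees", {
  bal <- lcsmsa:::new_guide_tree(
    matrix(c(-1L, -2L, -3L, -4L, 1L, 2L), 3, 2, byrow = TRUE),
    c(1, 1, 2), paste0("s", 1:4), "manual")
  expect_equal(sackin_index(bal), list(raw = 8, normalized = 2))
  two <- slink_tree(distance_rows(matrix(c(0, 3, 3, 0), 2)))
  expect_equal(two$height, 3)
  expect_equal(sackin_index(two), list(raw = 2, normalized = 1))
})

test_that("Newick round-trips topology and validates labels", {
  f <- withr::local_tempfile(lines = "((a,b),c);")
  tr <- parse_newick(f, ids = c("a", "b", "c"))
  expect_equal(tr$k, 3L)
  expect_equal(sort(lcsmsa:::leaf_depths(tr)), c(1, 2, 2))
  expect_error(parse_newick(f, ids = c("a", "b", "d")),
               "not in sequence set|missing from Newick")
  f2 <- withr::local_tempfile(lines = "(a,b,c);")
  expect_error(parse_newick(f2, ids = c("a", "b", "c")), "binary")

  set.seed(13)
  for (t in 1:20) {
    k <- sample(3:25, 1)
    d <- random_dist(k)
    tr <- slink_tree(distance_rows(d), labels = paste0("L", 1:k))
    fx <- withr::local_tempfile()
    write_newick(tr, fx)
    back <- parse_newick(fx, ids = tr$labels)
    ## identical topology: same clade (leaf-set) family
    clades <- function(x) {
      cs <- lapply(seq_len(x$k - 1L), function(r) {
        leaves <- function(ref) if (ref < 0L) -ref
          else unlist(lapply(x$merge[ref, ], leaves))
        sort(leaves(r))
      })
      cs[order(vapply(cs, paste, "", collapse = ","))]
    }
    expect_identical(clades(back), clades(tr))
  }
})

test_that("covering fractions and their Monte-Carlo baseline", {
  bal <- lcsmsa:::new_guide_tree(
    matrix(c(-1L, -2L, -3L, -4L, 1L, 2L), 3, 2, byrow = TRUE),
    c(1, 1, 2), paste0("s", 1:4), "manual")
  expect_equal(covering_fraction(bal, c("s1", "s2")), 0.5)
  expect_equal(covering_fraction(bal, paste0("s", 1:4)), 1)
  expect_equal(covering_fraction(bal, c("s1", "s3")), 1)
  expect_error(covering_fraction(bal, character(0)), "empty")
  expect_error(covering_fraction(bal, "nope"), "unknown leaf")

  ## exhaustive expectation on the balanced 4-leaf tree, subsets of size 2:
  ## cherries (2 of 6 subsets) cover 1/2, the rest cover 1
  exp_mean <- (2 * 0.5 + 4 * 1) / 6
  mc <- mc_covering_fraction(bal, 2, trials = 3000, seed = 7)
  expect_equal(mc, exp_mean, tolerance = 0.03)
  ## reproducible for a fixed seed
  expect_identical(mc_covering_fraction(bal, 2, 100, 3),
                   mc_covering_fraction(bal, 2, 100, 3))
})
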