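mx <- load_matrix("MIQS")

test_that("column costs are counter-weighted pair-score sums", {
  md <- gap_model(k = 3)
  ## single gapless sequence: table row j = matrix row of residue j
  s <- as_seqset(c(a = "AWC"))
  p <- profile_from_sequence(s$sequences[[1]])
  cc <- column_costs(p, mx, md)
  expect_equal(unname(cc[2, 1:25]), unname(mx$scores["W", ]))
  ## pure-residue column of k members vs Ge: k * scaled Ge
  aln <- as_alignment(c(a = "AC", b = "AC", c = "AC"))
  p3 <- profile_from_alignment(aln)
  cc3 <- column_costs(p3, mx, md)
  expect_equal(unname(cc3[1, lcsmsa:::GE_CODE]), 3 * md$ge)

  set.seed(40)
  P <- lcsmsa:::pair_score_matrix(mx, md)
  for (t in 1:10) {
    aln <- random_alignment(sample(2:4, 1), sample(3:8, 1))
    p <- profile_from_alignment(aln)
    cc <- column_costs(p, mx, md)
    ## brute force: sum over member symbols per column
    typed <- t(matrix(vapply(p$members, realize_typed, integer(p$width)),
                      nrow = p$width))
    for (j in seq_len(p$width)) for (sym in c(1L, 7L, lcsmsa:::GO_CODE))
      expect_equal(unname(cc[j, sym]), sum(P[typed[, j], sym]))
  }
})

test_that("sequence-pair DP equals the independent Gotoh oracle (>=1000 pairs)", {
  set.seed(41)
  md <- gap_model(k = 2)
  S <- mx$scores
  for (t in 1:1000) {
    A <- sample.int(20L, sample(1:30, 1), TRUE)
    B <- sample.int(20L, sample(1:30, 1), TRUE)
    r <- align_seq_seq(lcsmsa:::new_sequence("a", A),
                       lcsmsa:::new_sequence("b", B), mx, md)
    expect_equal(r$score, oracle_gotoh(A, B, S, md$go, md$ge, md$to, md$te))
  }
})

test_that("worked pair example matches Gotoh with free terminal gaps", {
  toy <- toy_matrix()
  md <- gap_model(go = -2, ge = -1, to = 0, te = 0, k = 2)
  s <- as_seqset(c(x = "CC", y = "CAC"))
  r <- align_seq_seq(s$sequences[[1]], s$sequences[[2]], toy, md)
  expect_equal(r$score,
               oracle_gotoh(encode_residues("CC"), encode_residues("CAC"),
                            toy$scores, -2, -1, 0, 0))
  ## identical sequences: n matches, no gaps
  sid <- as_seqset(c(x = "WWHH", y = "WWHH"))
  rid <- align_seq_seq(sid$sequences[[1]], sid$sequences[[2]], toy, md)
  expect_equal(rid$score, 4)
  expect_equal(rid$ops, rep(1L, 4))
})

test_that("reported score equals the model score of the realized merge", {
  set.seed(42)
  for (t in 1:30) {
    kx <- sample(1:3, 1); ky <- sample(1:3, 1)
    ax <- random_alignment(kx, sample(2:6, 1))
    ay <- random_alignment(ky, sample(2:6, 1))
    px <- profile_from_alignment(ax)
    py <- profile_from_alignment(ay, seq_index = kx + seq_len(ky))
    md <- gap_model(k = kx + ky)
    r <- align_profiles(px, py, mx, md)
    expect_equal(r$score,
                 model_score(profile_alignment(r$profile), mx, md))
  }
})

test_that("tiny-profile DP dominates exhaustive matchings, exactly for gapless inputs", {
  set.seed(43)
  md <- gap_model(k = 4)
  for (t in 1:12) {
    gapless <- t <= 6
    wx <- sample(2:4, 1); wy <- sample(2:4, 1)
    ax <- random_alignment(2, wx, gap_prob = if (gapless) 0 else 0.25)
    ay <- random_alignment(2, wy, gap_prob = if (gapless) 0 else 0.25)
    px <- profile_from_alignment(ax)
    py <- profile_from_alignment(ay, seq_index = 2 + seq_len(2))
    r <- align_profiles(px, py, mx, md)
    best <- -Inf
    for (ops in oracle_enum_matchings(px$width, py$width)) {
      mat <- oracle_merge_mats(
        t(sapply(px$members, realize)), t(sapply(py$members, realize)), ops)
      sc <- model_score(lcsmsa:::new_alignment(mat, paste0("s", 1:4)), mx, md)
      best <- max(best, sc)
    }
    if (gapless) expect_equal(r$score, best)
    expect_gte(r$score + 1e-9, best)
  }
})

test_that("specialized DP variants match the general routine", {
  set.seed(44)
  md <- gap_model(k = 4)
  for (t in 1:100) {
    A <- sample.int(20L, sample(1:25, 1), TRUE)
    B <- sample.int(20L, sample(1:25, 1), TRUE)
    sa <- lcsmsa:::new_sequence("a", A); sb <- lcsmsa:::new_sequence("b", B)
    r1 <- align_seq_seq(sa, sb, mx, md)
    r2 <- align_profiles(profile_from_sequence(sa, 1L),
                         profile_from_sequence(sb, 2L), mx, md)
    expect_identical(r1$ops, r2$ops)
    expect_equal(r1$score, r2$score)
  }
  for (t in 1:10) {
    ax <- random_alignment(3, sample(3:8, 1))
    px <- profile_from_alignment(ax)
    B <- sample.int(20L, sample(2:10, 1), TRUE)
    sb <- lcsmsa:::new_sequence("b", B)
    r1 <- align_profile_seq(px, sb, mx, md)
    r2 <- align_profiles(px, profile_from_sequence(sb, 4L), mx, md)
    expect_identical(r1$ops, r2$ops)
    expect_equal(r1$score, r2$score)
  }
  ## degenerate length-1 sequences
  r <- align_seq_seq(lcsmsa:::new_sequence("a", 5L),
                     lcsmsa:::new_sequence("b", 7L), mx, md)
  expect_equal(length(r$ops) >= 1L, TRUE)
})

test_that("progressive alignment satisfies the pipeline invariants", {
  set.seed(45)
  set <- random_seqset(8, c(20L, 40L))
  tree <- slink_tree(distance_rows(set))
  aln <- progressive_align(set, tree)
  expect_equal(nrow(aln$mat), 8L)
  expect_silent(lcsmsa:::assert_valid_alignment(aln, set))

  ## k = 2 equals the bare pairwise variant
  two <- as_seqset(c(a = "ACDEFGH", b = "ACWEFH"))
  t2 <- slink_tree(distance_rows(two))
  a2 <- progressive_align(two, t2)
  md <- gap_model(k = 2)
  r2 <- align_seq_seq(two$sequences[[1]], two$sequences[[2]], mx, md)
  expect_equal(alignment_strings(a2),
               alignment_strings(profile_alignment(r2$profile)))

  ## tree/set mismatch errors
  expect_error(progressive_align(two, tree), "leaves")
})

test_that("substitution-only families align without gaps", {
  fam <- generate_family(k = 5, root_len = 60, sub_rate = 0.1,
                         indel_rate = 0, seed = 3)
  aln <- msa_align(fam$sequences)
  expect_equal(aln$width, 60L)
  expect_true(all(aln$mat != 0L))
})

test_that("input order permutation with a relabeled tree permutes rows only", {
  set.seed(46)
  set <- random_seqset(6, c(15L, 25L))
  tree <- slink_tree(distance_rows(set))
  aln <- progressive_align(set, tree)

  perm <- sample(6)
  set2 <- lcsmsa:::new_seqset(set$sequences[perm])
  ## relabel tree leaves to the permuted positions
  tree2 <- tree
  remap <- match(seq_len(6), perm)
  tree2$merge[tree2$merge < 0] <- -remap[-tree2$merge[tree2$merge < 0]]
  tree2$labels <- seqset_ids(set2)
  aln2 <- progressive_align(set2, tree2)
  ord <- match(aln$ids, aln2$ids)
  expect_equal(alignment_strings(aln2)[ord], alignment_strings(aln))
})
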