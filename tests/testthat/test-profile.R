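fig1_row <- "--CA--H-F---Q-GAC--DLM----FA-P-S"

test_that("gapped representation reproduces the worked example", {
  gs <- gapped_from_string(fig1_row)
  expect_equal(length(gs$symbols), 15L)
  expect_equal(gs$no_gaps,
               c(2L, 0L, 2L, 1L, 3L, 1L, 0L, 0L, 2L, 0L, 0L, 4L, 0L, 1L, 1L,
                 0L))                                  # guard slot last
  expect_equal(gapped_width(gs), 32L)
  expect_equal(gs$dps[1], 32L)                         # root = width
  ## first leaf covers slots 1..2: two residues plus their leading gaps
  expect_equal(gs$dps[8], 4L)
  ## heap rule dps[i] = dps[2i] + dps[2i+1]
  for (i in 1:7) expect_equal(gs$dps[i], gs$dps[2 * i] + gs$dps[2 * i + 1])
  expect_equal(decode_residues(realize(gs)), fig1_row)
})

test_that("gapless rows and round-trips", {
  gs <- gapped_from_string("ACDE")
  expect_equal(gs$no_gaps, rep(0L, 5))
  expect_equal(gapped_width(gs), 4L)
  expect_error(gapped_from_string("----"), "all-gap")

  set.seed(20)
  for (t in 1:50) {
    aln <- random_alignment(1, sample(2:40, 1))
    row <- aln$mat[1, ]
    gs <- gapped_from_string(row)
    expect_identical(realize(gs), row)
  }
})

test_that("coordinate mapping agrees with a linear scan of the realized row", {
  gs <- gapped_from_string(fig1_row)
  expect_equal(column_to_position(gs, 2L), 1L)         # the 'C'
  expect_true(is.na(column_to_position(gs, 0L)))       # leading gap
  expect_error(column_to_position(gs, 32L), "out of range")

  set.seed(21)
  for (t in 1:30) {
    aln <- random_alignment(1, sample(2:50, 1))
    row <- aln$mat[1, ]
    gs <- gapped_from_string(row)
    respos <- which(row != 0L)
    for (col in seq_along(row) - 1L) {
      want <- if (row[col + 1L] == 0L) NA_integer_
        else match(col + 1L, respos)
      expect_identical(column_to_position(gs, col), want)
    }
    for (s in seq_along(respos))
      expect_equal(position_to_column(gs, s), respos[s] - 1L)
  }
})

test_that("gap-column insertion updates width, members and counters", {
  p <- profile_from_alignment(as_alignment(c(a = "ACD", b = "AWD")))
  p2 <- insert_gap_columns(p, 0L, 1L)
  expect_equal(p2$width, 4L)
  aln <- profile_alignment(p2)
  expect_equal(alignment_strings(aln), c("-ACD", "-AWD"))
  ## inserted column counts two terminal opens
  expect_equal(unname(p2$counters[lcsmsa:::TO_CODE, 1]), 2L)

  set.seed(22)
  for (t in 1:40) {
    aln <- random_alignment(sample(2:5, 1), sample(3:12, 1))
    p <- profile_from_alignment(aln)
    w0 <- p$width
    ins <- 0L
    for (q in 1:6) {
      col <- sample(0:p$width, 1)
      cnt <- sample(1:3, 1)
      p <- insert_gap_columns(p, col, cnt)
      ins <- ins + cnt
    }
    expect_equal(p$width, w0 + ins)                    # width conservation
    expect_identical(unname(p$counters),
                     unname(lcsmsa:::recount_profile(p)))
    expect_equal(colSums(p$counters), rep(p$k, p$width))
  }
})

test_that("profile counters always sum to the member count per column", {
  set.seed(23)
  aln <- random_alignment(4, 15)
  p <- profile_from_alignment(aln)
  expect_equal(colSums(p$counters), rep(4L, p$width))
  expect_identical(unname(p$counters), unname(lcsmsa:::recount_profile(p)))
})

test_that("profile merging moves members and conserves content", {
  set <- as_seqset(c(a = "ACDE", b = "ACDE"))
  px <- profile_from_sequence(set$sequences[[1]], 1L)
  py <- profile_from_sequence(set$sequences[[2]], 2L)
  merged <- merge_profiles(px, py, rep(1L, 4))         # identity matching
  expect_equal(merged$width, 4L)
  expect_equal(merged$k, 2L)
  expect_equal(colSums(merged$counters), rep(2L, 4))
  expect_equal(unname(merged$counters[1, ]), c(2L, 0L, 0L, 0L))  # A column

  expect_error(merge_profiles(px, py, c(1L, 1L, 1L)), "consume")

  set.seed(24)
  for (t in 1:20) {
    ax <- random_alignment(sample(1:3, 1), sample(2:6, 1))
    ay <- random_alignment(sample(1:3, 1), sample(2:6, 1))
    px <- profile_from_alignment(ax)
    py <- profile_from_alignment(ay, seq_index = nrow(ax$mat) +
                                   seq_len(nrow(ay$mat)))
    ops <- oracle_enum_matchings(px$width, py$width)[[1]]
    m <- merge_profiles(px, py, ops)
    expect_equal(m$k, px$k + py$k)
    expect_equal(m$width, length(ops))
    expect_identical(unname(m$counters), unname(lcsmsa:::recount_profile(m)))
    ## gap-stripped realized rows equal the original sequences
    back <- strip_gaps(profile_alignment(m))
    orig <- c(lapply(seq_len(nrow(ax$mat)), function(i) {
      r <- ax$mat[i, ]; r[r != 0L] }),
      lapply(seq_len(nrow(ay$mat)), function(i) {
        r <- ay$mat[i, ]; r[r != 0L] }))
    expect_identical(lapply(back$sequences, `[[`, "res"), orig)
  }
})

test_that("storage stays linear in the residue count", {
  gs <- gapped_from_string(strrep("A", 1000))
  slots <- length(gs$symbols) + length(gs$no_gaps) + length(gs$dps)
  expect_lt(slots, 6 * 1000)
})
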