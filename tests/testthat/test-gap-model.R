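test_that("gap scaler: unit below threshold, logarithmic growth beyond", {
  expect_equal(gap_scaler(10), 1)
  expect_equal(gap_scaler(45), 1)
  expect_equal(gap_scaler(90), 1 + log2(2) / 7)
  ## continuity at the threshold and monotonicity
  expect_equal(gap_scaler(45 + 1e-9), 1, tolerance = 1e-9)
  ks <- c(1:45, 46, 60, 90, 200, 1000, 1e5)
  expect_true(all(diff(gap_scaler(ks)) >= 0))
  expect_true(all(gap_scaler(ks) >= 1))
})

test_that("the scaler multiplies all four penalties", {
  m <- gap_model(k = 90)
  s <- gap_scaler(90)
  expect_equal(m$go, -14.85 * s)
  expect_equal(m$ge, -1.25 * s)
  expect_equal(m$to, -0.66 * s)
  expect_equal(m$te, -0.66 * s)
  expect_warning(gap_model(go = -1, ge = -5, k = 2), "extension")
})

test_that("pairwise symbol scores delegate to matrix, penalties and zero", {
  mx <- load_matrix("MIQS")
  md <- gap_model(k = 2)
  expect_equal(pair_gap_score("A", "A", mx, md), mx$scores["A", "A"])
  expect_equal(pair_gap_score("A", "Ge", mx, md), md$ge)
  expect_equal(pair_gap_score("Go", "Te", mx, md), 0)
  expect_equal(gap_score("To", md), md$to)
  expect_equal(gap_score(lcsmsa:::GE_CODE, md), md$ge)
})

## --- the six correction situations -----------------------------------------

test_that("S1: terminal gap open at the right becomes To + neighbour Te", {
  ## row starts "-FLP": the existing leading gap is a terminal open
  gs <- gapped_from_string("-FLP")
  res <- classify_inserted_gap(gs, 0L)
  expect_equal(res$type_name, "To")
  expect_equal(res$retype,
               list(col = 0L, from = lcsmsa:::TO_CODE, to = lcsmsa:::TE_CODE))
})

test_that("S2: terminal gap extension at the left keeps extending", {
  ## "--FLP": inserting after the Te at column 1
  gs <- gapped_from_string("--FLP")
  res <- classify_inserted_gap(gs, 2L)
  expect_equal(res$type_name, "Te")
  expect_null(res$retype)
})

test_that("S3: insertion inside an interior gap series is an extension", {
  gs <- gapped_from_string("FL--P")
  res <- classify_inserted_gap(gs, 3L)
  expect_equal(res$type_name, "Ge")
  expect_null(res$retype)
})

test_that("S4: gap open at the right becomes Go + neighbour Ge", {
  gs <- gapped_from_string("F-LP")
  res <- classify_inserted_gap(gs, 1L)
  expect_equal(res$type_name, "Go")
  expect_equal(res$retype,
               list(col = 1L, from = lcsmsa:::GO_CODE, to = lcsmsa:::GE_CODE))
})

test_that("S5: a lone gap between residues opens", {
  gs <- gapped_from_string("FLP")
  res <- classify_inserted_gap(gs, 2L)     # between L and P
  expect_equal(res$type_name, "Go")
  expect_null(res$retype)
})

test_that("S6: after a terminal gap open the insertion extends it", {
  gs <- gapped_from_string("-FLP")
  res <- classify_inserted_gap(gs, 1L)     # right after the To
  expect_equal(res$type_name, "Te")
  expect_null(res$retype)
})

test_that("terminal insertions at bare row ends open terminal series", {
  gs <- gapped_from_string("FLP")
  expect_equal(classify_inserted_gap(gs, 0L)$type_name, "To")
  expect_equal(classify_inserted_gap(gs, 3L)$type_name, "To")
  ## second insertion at column 0 sees the new To at its right (S1 again)
  p <- profile_from_alignment(as_alignment(c(a = "FLP")))
  p <- insert_gap_columns(p, 0L, 1L)
  res <- classify_inserted_gap(p$members[[1]], 0L)
  expect_equal(res$type_name, "To")
  expect_equal(res$retype$to, lcsmsa:::TE_CODE)
})

test_that("incremental classification equals from-scratch row reclassification", {
  set.seed(30)
  for (t in 1:300) {
    aln <- random_alignment(1, sample(3:15, 1))
    gs <- gapped_from_string(aln$mat[1, ])
    col <- sample(0:gapped_width(gs), 1)
    ins <- lcsmsa:::classify_gap_insertion(gs, col, 1L)
    ## apply incrementally
    typed_inc <- append(realize_typed(gs), ins$types[1], after = col)
    if (!is.null(ins$retype))
      typed_inc[ins$retype$col + 2L] <- ins$retype$to
    ## oracle: realize, insert a plain gap, retype the whole row
    row2 <- append(realize(gs), 0L, after = col)
    expect_identical(typed_inc, lcsmsa:::typed_row(row2))
  }
})
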