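## Alignment objective (model score) and SP/TC benchmark scores.

#' Sum-of-pairs model score of an alignment
#'
#' The summed alignment score of every unordered sequence pair: per column,
#' residue pairs score by the substitution matrix, a residue against a gap
#' scores the gap's type penalty (types assigned per row from scratch:
#' runs touching either end of the row are terminal, To + Te per extra
#' column; interior runs Go + Ge), and gap-gap pairs score 0.
#'
#' @param aln an `msa_alignment` (or `msa_profile`).
#' @param matrix an `msa_submatrix`.
#' @param model an `msa_gap_model`.
#' @return numeric score.
#' @export
model_score <- function(aln, matrix, model) {
  if (inherits(aln, "msa_profile")) aln <- profile_alignment(aln)
  if (nrow(aln$mat) == 1L) return(0)
  typed <- t(matrix(vapply(seq_len(nrow(aln$mat)),
                           function(i) typed_row(aln$mat[i, ]),
                           integer(ncol(aln$mat))), nrow = ncol(aln$mat)))
  counters <- count_typed_rows(typed)
  score_from_counters(counters, matrix, model)
}

## Column-wise sum over unordered pairs via the counter quadratic form.
score_from_counters <- function(counters, matrix, model) {
  P <- pair_score_matrix(matrix, model)
  q <- colSums(counters * (P %*% counters))    # c' P c per column
  selfs <- colSums(counters * diag(P))         # pairs of a symbol with itself
  sum(q - selfs) / 2
}

#' Sum-of-pairs and total-column scores against a reference alignment
#'
#' The reference rows must be a subset of the test rows by id, with
#' identical residues after gap stripping.  SP is the fraction of residue
#' pairs co-aligned in the reference that are also co-aligned in the test;
#' TC is the fraction of reference columns whose full residue content is
#' reproduced as a single test column.  Reference columns consisting only
#' of gaps are skipped in TC; pairs involving a gap are skipped in SP.
#'
#' @param test,ref `msa_alignment` objects.
#' @return list with `sp` and `tc`, both in `[0, 1]`.
#' @export
sp_tc <- function(test, ref) {
  idx <- match(ref$ids, test$ids)
  if (anyNA(idx))
    stop("reference id missing from test alignment: '",
         ref$ids[which(is.na(idx))[1L]], "'", call. = FALSE)
  kr <- nrow(ref$mat)
  ## residue-index -> column maps
  colmap <- function(row) which(row != GAP_CODE)
  ref_cols <- lapply(seq_len(kr), function(i) colmap(ref$mat[i, ]))
  test_cols <- lapply(idx, function(i) colmap(test$mat[i, ]))
  for (i in seq_len(kr)) {
    if (length(ref_cols[[i]]) != length(test_cols[[i]]) ||
        !identical(ref$mat[i, ref_cols[[i]]],
                   test$mat[idx[i], test_cols[[i]]]))
      stop("residues of '", ref$ids[i],
           "' differ between test and reference", call. = FALSE)
  }
  ## test column of the r-th residue of row i
  tpos <- function(i) {
    v <- rep(NA_integer_, ref$width)
    v[ref_cols[[i]]] <- test_cols[[i]]
    v
  }
  tmat <- vapply(seq_len(kr), tpos, integer(ref$width))  # ref-col x row
  sp_hit <- 0L; sp_tot <- 0L; tc_hit <- 0L; tc_tot <- 0L
  for (cc in seq_len(ref$width)) {
    cols <- tmat[cc, ]
    present <- !is.na(cols)
    np <- sum(present)
    if (np == 0L) next                       # all-gap reference column
    tc_tot <- tc_tot + 1L
    if (length(unique(cols[present])) == 1L) tc_hit <- tc_hit + 1L
    if (np >= 2L) {
      tab <- table(cols[present])
      sp_tot <- sp_tot + np * (np - 1L) / 2L
      sp_hit <- sp_hit + sum(tab * (tab - 1L) / 2L)
    }
  }
  list(sp = if (sp_tot > 0L) sp_hit / sp_tot else NA_real_,
       tc = tc_hit / tc_tot)
}
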