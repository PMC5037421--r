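## Stage III: profile-profile dynamic programming and the progressive
## driver.
##
## The DP maximizes the summed pairwise score of the merged profile
## (within-profile pairs are constants with respect to the column matching;
## they are part of the reported score).  Gap open/extension and
## terminal/internal decisions inside the DP follow the DP cell position;
## the gap-type correction rules retype gaps per member row when the
## matching is realized, and the reported score is the model score of the
## realized merge -- recomputed whenever correction changes it (a package
## counter tracks how often that happens).

.msa_state <- new.env(parent = emptyenv())
.msa_state$correction_mismatches <- 0L

#' DP/realized score disagreement counter
#'
#' Number of profile merges (since package load or the last reset) whose
#' realized model score differed from the DP objective because gap-type
#' correction retyped gaps.
#'
#' @param reset reset the counter to zero.
#' @return the count, invisibly when resetting.
#' @export
correction_mismatches <- function(reset = FALSE) {
  if (reset) {
    .msa_state$correction_mismatches <- 0L
    return(invisible(0L))
  }
  .msa_state$correction_mismatches
}

#' Per-column alignment costs of a profile
#'
#' `table[j, s]` is the cost of aligning column `j` of the profile with one
#' occurrence of symbol `s` of the extended alphabet: the counter-weighted
#' sum of pairwise symbol scores.  With this table each DP cell evaluation
#' is a constant-time lookup per symbol.
#'
#' @param p an `msa_profile`.
#' @param matrix an `msa_submatrix`.
#' @param model an `msa_gap_model`.
#' @return numeric `width x 29` matrix.
#' @export
column_costs <- function(p, matrix, model) {
  P <- pair_score_matrix(matrix, model)
  t(p$counters) %*% P
}

## Gap-cost vectors for inserting a gap column into the *other* profile
## against each column of `p`: residues of the column each pay the penalty
## once per receiving sequence, existing gaps pay nothing.
gap_cost_vectors <- function(p, k_other, model) {
  nres <- colSums(p$counters[seq_len(N_RES), , drop = FALSE])
  list(open = nres * k_other * model$go, ext = nres * k_other * model$ge,
       topen = nres * k_other * model$to, text = nres * k_other * model$te)
}

dp_result <- function(ops, profile, score, dp_score) {
  structure(list(ops = ops, profile = profile, score = score,
                 dp_score = dp_score),
            class = "msa_dp_result")
}

#' @export
print.msa_dp_result <- function(x, ...) {
  cat("<profile DP result> score", format(x$score), "-",
      length(x$ops), "columns\n")
  invisible(x)
}

run_profile_dp <- function(x, y, smatch, matrix, model) {
  gy <- gap_cost_vectors(x, y$k, model)   # gap column into Y, vs X columns
  gx <- gap_cost_vectors(y, x$k, model)   # gap column into X, vs Y columns
  res <- .affine_dp_cpp(smatch, gy$open, gy$ext, gy$topen, gy$text,
                        gx$open, gx$ext, gx$topen, gx$text)
  within <- 0
  if (x$k > 1L) within <- within + score_from_counters(
    recount_typed(x), matrix, model)
  if (y$k > 1L) within <- within + score_from_counters(
    recount_typed(y), matrix, model)
  merged <- merge_profiles(x, y, res$ops)
  realized <- model_score(merged, matrix, model)
  dp_total <- res$score + within
  if (abs(realized - dp_total) > 1e-6 * max(1, abs(realized)))
    .msa_state$correction_mismatches <- .msa_state$correction_mismatches + 1L
  dp_result(res$ops, merged, realized, dp_total)
}

recount_typed <- function(p) {
  count_typed_rows(realize_members(p, realize_typed))
}

#' Align two profiles
#'
#' Three-state affine DP (match / gap column in X / gap column in Y) over
#' the summed pair score, with terminal penalties on runs flanking either
#' profile and direct transitions between the two gap states (the
#' double-gap-column check).  When both inputs are single gapless
#' sequences the score equals a textbook affine aligner with terminal gap
#' penalties, exactly.
#'
#' @param x,y `msa_profile` objects.
#' @param matrix an `msa_submatrix`.
#' @param model an `msa_gap_model`.
#' @return an `msa_dp_result`: `ops` (1 = MATCH, 2 = gap column in X,
#'   3 = gap column in Y), the merged `profile`, the realized model
#'   `score`, and the DP objective `dp_score`.
#' @export
align_profiles <- function(x, y, matrix, model) {
  stopifnot(x$width >= 1L, y$width >= 1L)
  smatch <- column_costs(x, matrix, model) %*% y$counters
  run_profile_dp(x, y, smatch, matrix, model)
}

#' Specialized DP variants
#'
#' `align_seq_seq()` aligns two single sequences and `align_profile_seq()`
#' a profile with one sequence, skipping the counter machinery where a
#' direct score lookup suffices.  Results (scores and realized
#' alignments) are identical to [align_profiles()] on the same inputs.
#'
#' @param a,b `msa_sequence` objects (or single-sequence profiles).
#' @param x an `msa_profile`.
#' @inheritParams align_profiles
#' @return an `msa_dp_result`.
#' @export
align_seq_seq <- function(a, b, matrix, model) {
  pa <- as_single_profile(a, 1L)
  pb <- as_single_profile(b, 2L)
  P <- pair_score_matrix(matrix, model)
  smatch <- P[pa$members[[1L]]$symbols, pb$members[[1L]]$symbols,
              drop = FALSE]
  run_profile_dp(pa, pb, smatch, matrix, model)
}

#' @rdname align_seq_seq
#' @export
align_profile_seq <- function(x, b, matrix, model) {
  pb <- as_single_profile(b, max(x$seq_index) + 1L)
  smatch <- column_costs(x, matrix, model)[, pb$members[[1L]]$symbols,
                                           drop = FALSE]
  run_profile_dp(x, pb, smatch, matrix, model)
}

as_single_profile <- function(s, index) {
  if (inherits(s, "msa_profile")) {
    stopifnot(s$k == 1L)
    return(s)
  }
  profile_from_sequence(s, index)
}

#' Progressive alignment along a guide tree
#'
#' Post-order fold of [align_profiles()] over the tree: leaves become
#' single-sequence profiles, each internal node merges its children.  The
#' single-sequence DP specializations are dispatched automatically.  Rows
#' of the returned alignment follow the input order of the sequence set.
#'
#' @param set an `msa_seqset`.
#' @param tree an `msa_guide_tree` whose leaf set matches the sequences
#'   (by index; labels are checked when present).
#' @param matrix an `msa_submatrix` (default MIQS).
#' @param model an `msa_gap_model` (default: [gap_model()] with `k` set
#'   from the input).
#' @return an `msa_alignment`.
#' @export
progressive_align <- function(set, tree, matrix = load_matrix("MIQS"),
                              model = gap_model(k = set$k)) {
  stopifnot(inherits(set, "msa_seqset"), inherits(tree, "msa_guide_tree"))
  if (tree$k != set$k)
    stop("guide tree has ", tree$k, " leaves for ", set$k, " sequences",
         call. = FALSE)
  if (!setequal(tree$labels, seqset_ids(set)) &&
      !all(tree$labels == paste0("s", seq_len(set$k))))
    stop("guide tree labels do not match the sequence ids", call. = FALSE)
  profiles <- vector("list", set$k - 1L)
  node_profile <- function(ref) {
    if (ref < 0L) profile_from_sequence(set$sequences[[-ref]], -ref)
    else profiles[[ref]]
  }
  for (r in seq_len(set$k - 1L)) {
    px <- node_profile(tree$merge[r, 1L])
    py <- node_profile(tree$merge[r, 2L])
    res <- if (px$k == 1L && py$k == 1L) align_seq_seq(px, py, matrix, model)
           else if (py$k == 1L) align_profile_seq(px, py, matrix, model)
           else if (px$k == 1L) {
             ## keep (x, y) roles: make the single sequence profile y
             align_profile_seq(py, px, matrix, model)
           } else align_profiles(px, py, matrix, model)
    ## free children as they are consumed
    if (tree$merge[r, 1L] > 0L) profiles[tree$merge[r, 1L]] <- list(NULL)
    if (tree$merge[r, 2L] > 0L) profiles[tree$merge[r, 2L]] <- list(NULL)
    profiles[[r]] <- res$profile
  }
  final <- profiles[[set$k - 1L]]
  aln <- profile_alignment(final)
  aln$ids <- seqset_ids(set)
  assert_valid_alignment(aln, set)
  aln
}
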