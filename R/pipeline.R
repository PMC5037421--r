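## End-to-end pipeline: similarities -> guide tree -> progressive merge ->
## optional refinement.

#' Align a protein family
#'
#' Runs the four pipeline stages with the package defaults: LCS/indel
#' pairwise distances, a SLINK single-linkage guide tree, MIQS-scored
#' progressive profile merging with set-size-scaled four-type affine gap
#' penalties, and automatic column-oriented refinement (for families of at
#' most `cfg$k_max` sequences).
#'
#' @param set an `msa_seqset` (see [read_fasta()], [as_seqset()]).
#' @param guide_tree `"sl"`, `"upgma"`, `"chained"`, or an
#'   `msa_guide_tree` (e.g. from [parse_newick()]).
#' @param matrix an `msa_submatrix` (default MIQS).
#' @param model an `msa_gap_model`; default [gap_model()] with `k` taken
#'   from the input set.
#' @param cfg an `msa_refine_config`.
#' @param seed seed for the chained-tree order and refinement column
#'   choice (overrides `cfg$seed`).
#' @return the final `msa_alignment`; attributes `"guide_tree"` and
#'   `"refine_trace"` expose the intermediate tree and the accepted-score
#'   sequence.
#' @export
msa_align <- function(set, guide_tree = "sl", matrix = load_matrix("MIQS"),
                      model = gap_model(k = set$k),
                      cfg = refine_config(), seed = NULL) {
  stopifnot(inherits(set, "msa_seqset"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (set$k == 1L) {
    s <- set$sequences[[1L]]
    return(new_alignment(matrix(s$res, 1L), s$id))
  }
  tree <- if (inherits(guide_tree, "msa_guide_tree")) guide_tree
    else switch(match.arg(guide_tree, c("sl", "upgma", "chained")),
                sl = slink_tree(distance_rows(set)),
                upgma = upgma_tree(distance_rows(set)),
                chained = chained_tree(set$k, seed = cfg$seed,
                                       labels = seqset_ids(set)))
  aln <- progressive_align(set, tree, matrix, model)
  aln <- refine(aln, matrix, model, cfg)
  attr(aln, "guide_tree") <- tree
  aln
}
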