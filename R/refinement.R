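## Stage IV: column-oriented iterative refinement.
##
## Each iteration picks a random column containing at least one gap,
## splits the alignment rows by gap presence in that column, drops the
## all-gap columns of each part, realigns the two subprofiles and accepts
## the proposal iff its model score is strictly higher (equal-score
## proposals are rejected to prevent cycling).

#' Refinement configuration
#'
#' @param iterations number of proposal iterations (default 100).
#' @param k_max in `auto` mode refinement runs only for `k <= k_max`
#'   sequences (default 1000).
#' @param seed RNG seed for the column choice (default 0: default runs are
#'   reproducible).
#' @param mode `"auto"`, `"on"` (ignore `k_max`) or `"off"`.
#' @return an `msa_refine_config`.
#' @export
refine_config <- function(iterations = 100L, k_max = 1000L, seed = 0L,
                          mode = c("auto", "on", "off")) {
  stopifnot(iterations >= 0L)
  structure(list(iterations = as.integer(iterations),
                 k_max = as.integer(k_max), seed = as.integer(seed),
                 mode = match.arg(mode)),
            class = "msa_refine_config")
}

## Drop all-gap columns of a row subset and return the subprofile.
subprofile <- function(aln, rows) {
  sub <- aln$mat[rows, , drop = FALSE]
  keep <- colSums(sub != GAP_CODE) > 0L
  profile_from_alignment(new_alignment(sub[, keep, drop = FALSE],
                                       aln$ids[rows]),
                         seq_index = which(rows))
}

#' Iteratively refine an alignment
#'
#' @param aln an `msa_alignment`.
#' @param matrix an `msa_submatrix`.
#' @param model an `msa_gap_model`.
#' @param cfg an `msa_refine_config`.
#' @return the refined `msa_alignment`, with attribute
#'   `"refine_trace"` holding the accepted score sequence (first entry:
#'   the initial score).
#' @export
refine <- function(aln, matrix = load_matrix("MIQS"),
                   model = gap_model(k = nrow(aln$mat)),
                   cfg = refine_config()) {
  k <- nrow(aln$mat)
  if (cfg$mode == "off" || (cfg$mode == "auto" && k > cfg$k_max) ||
      k < 2L || cfg$iterations == 0L) {
    attr(aln, "refine_trace") <- model_score(aln, matrix, model)
    return(aln)
  }
  cur <- aln
  cur_score <- model_score(cur, matrix, model)
  trace <- cur_score
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      has_gap <- colSums(cur$mat == GAP_CODE) > 0L
      cand <- which(has_gap)
      if (length(cand) == 0L) break
      cc <- cand[sample.int(length(cand), 1L)]
      gap_rows <- cur$mat[, cc] == GAP_CODE
      ## the chosen column has >= 1 gap and >= 1 residue, so neither
      ## part is empty
      px <- subprofile(cur, !gap_rows)
      py <- subprofile(cur, gap_rows)
      res <- align_profiles(px, py, matrix, model)
      if (res$score > cur_score) {
        cand_aln <- profile_alignment(res$profile)
        cur <- cand_aln
        cur_score <- res$score
        trace <- c(trace, cur_score)
      }
    }
  })
  attr(cur, "refine_trace") <- trace
  cur
}
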